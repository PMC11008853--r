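#' Generate synthetic replicates for a scenario
#'
#' Simulates the scenario's calibrated rates on its sampling grid from a
#' drug-free start, observes `y = x3` directly, and perturbs the curve with
#' the replicate-level scale factor and per-sample multiplicative noise of
#' the [noise_model()]. Negative values are clipped to zero. Deterministic
#' given `seed`.
#'
#' @param sc a [scenario()].
#' @param noise a [noise_model()]; use `noise_model(0, 0)` for noise-free
#'   replicates.
#' @param n_replicates number of replicates (default: the scenario's).
#' @param seed integer seed.
#' @return A list: `replicates` (list of [observation_series()]),
#'   `noise_free` (the model curve as an [observation_series()]) and
#'   `truth` (the generating [rate_parameters()]).
#' @export
generate_scenario <- function(sc, noise = noise_model(),
                              n_replicates = NULL, seed = 1L) {
  if (!inherits(sc, "scenario")) stop("sc must be a scenario", call. = FALSE)
  if (!inherits(noise, "noise_model")) stop("noise must be a noise_model", call. = FALSE)
  if (is.null(n_replicates)) n_replicates <- sc$n_replicates
  times <- scenario_times(sc)
  tr <- simulate_closed_form(sc$params, times = times)
  y0 <- tr$states[, 3]
  noise_free <- observation_series(times, y0, unit = sc$unit,
                                   replicate = 0L, scenario_id = sc$id)
  sdlog <- sqrt(log1p(noise$cv_replicate^2))
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      scale_r <- if (sdlog > 0) {
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else 1
      eps <- if (noise$cv_sample > 0) {
        1 + noise$cv_sample * stats::rnorm(length(y0))
      } else rep(1, length(y0))
      observation_series(times, pmax(y0 * scale_r * eps, 0), unit = sc$unit,
                         replicate = r, scenario_id = sc$id)
    })
  })
  list(replicates = reps, noise_free = noise_free, truth = sc$params)
}

#' Convert sampled perfusate concentrations to cumulative mass per area
#'
#' Each collected sample holds the perfusate pumped during one sampling
#' interval: volume = flow rate x interval. The drug mass in a sample is
#' concentration x volume, and the cumulative penetrated mass is the running
#' sum normalized to the diffusion area.
#'
#' @param concentrations nonnegative sample concentrations in mass/mL (one
#'   per collected fraction, in collection order).
#' @param interval_min sampling interval in minutes.
#' @param device a [device_constants()] list.
#' @param unit output unit label (mass per cm2 matching the concentration's
#'   mass unit).
#' @param replicate,scenario_id passed to [observation_series()].
#' @return An [observation_series()] of cumulative mass per area at the end
#'   of each sampling interval.
#' @examples
#' # constant 1 ug/mL collected every 30 min: 0.12 ug per 120 uL sample,
#' # i.e. increments of 0.24 ug/cm2 over the 0.5 cm2 diffusion surface
#' concentration_to_cumulative_mass(rep(1, 4), 30)
#' @export
concentration_to_cumulative_mass <- function(concentrations, interval_min,
                                             device = device_constants(),
                                             unit = "ug/cm2",
                                             replicate = 1L,
                                             scenario_id = NA_character_) {
  conc <- as.numeric(concentrations)
  if (any(!is.finite(conc))) stop("concentrations must be finite", call. = FALSE)
  if (any(conc < 0)) {
    stop("concentrations must be nonnegative; got minimum ",
         format(min(conc)), call. = FALSE)
  }
  vol_ml <- device$flow_ul_min * interval_min / 1000
  mass <- conc * vol_ml
  cum <- cumsum(mass) / device$area_cm2
  times <- interval_min / 60 * seq_along(conc)
  observation_series(times, cum, unit = unit, replicate = replicate,
                     scenario_id = scenario_id)
}

#' Apply exclusion criteria to tabular records
#'
#' Drops records whose value is strictly below the criterion minimum or
#' strictly above the maximum (bounds inclusive: a value equal to a bound is
#' kept). Records whose attribute has no criterion are kept untouched.
#'
#' @param records data.frame with columns `id`, `attribute`, `value`.
#' @param criteria data.frame with columns `attribute`, `min`, `max` (e.g.
#'   [exclusion_criteria_default()]). Every criterion attribute must occur
#'   among the records.
#' @return A list: `kept` (surviving records), `report` (one row per
#'   exclusion: the record, the violated bound and its limit).
#' @export
apply_exclusion_criteria <- function(records, criteria) {
  need <- c("id", "attribute", "value")
  if (!all(need %in% names(records))) {
    stop("records must have columns id, attribute, value", call. = FALSE)
  }
  if (!all(c("attribute", "min", "max") %in% names(criteria))) {
    stop("criteria must have columns attribute, min, max", call. = FALSE)
  }
  if (any(criteria$min >= criteria$max)) {
    stop("criteria windows must satisfy min < max", call. = FALSE)
  }
  unknown <- setdiff(criteria$attribute, records$attribute)
  if (nrow(records) > 0 && length(unknown)) {
    stop("criteria target attributes absent from records: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(records))
  viol <- character(nrow(records)); lim <- rep(NA_real_, nrow(records))
  for (j in seq_len(nrow(criteria))) {
    sel <- records$attribute == criteria$attribute[j]
    low <- sel & records$value < criteria$min[j]
    high <- sel & records$value > criteria$max[j]
    viol[low] <- "below minimum"; lim[low] <- criteria$min[j]
    viol[high] <- "above maximum"; lim[high] <- criteria$max[j]
    keep <- keep & !(low | high)
  }
  report <- records[!keep, , drop = FALSE]
  if (nrow(report)) {
    report$violation <- viol[!keep]
    report$limit <- lim[!keep]
  } else {
    report$violation <- character(0)
    report$limit <- numeric(0)
  }
  rownames(report) <- NULL
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Summarize a set of observation series
#'
#' Computes the mean and standard error across replicates at each time
#' point (per scenario), per-replicate endpoints, and optionally the ratio
#' of endpoint means between named scenario pairs (disease vs control).
#'
#' @param series list of [observation_series()]; replicates of the same
#'   scenario must share the sampling grid.
#' @param ratio_pairs optional list of 2-vectors
#'   `c(numerator_id, denominator_id)`.
#' @return A list: `curve` (data.frame `scenario_id, time_h, mean, sem, n`),
#'   `endpoints` (data.frame `scenario_id, replicate, endpoint`), `ratios`
#'   (data.frame `numerator, denominator, ratio` or `NULL`).
#' @export
summarize_dataset <- function(series, ratio_pairs = NULL) {
  if (inherits(series, "observation_series")) series <- list(series)
  if (length(series) < 1L) stop("need at least one series", call. = FALSE)
  ids <- vapply(series, function(s) as.character(s$scenario_id), "")
  curve <- list(); endpoints <- list()
  for (id in unique(ids)) {
    grp <- series[ids == id]
    t0 <- grp[[1]]$times
    for (s in grp) {
      if (!isTRUE(all.equal(s$times, t0))) {
        stop("replicates of scenario '", id, "' have mismatched time grids",
             call. = FALSE)
      }
    }
    vals <- vapply(grp, function(s) s$values, numeric(length(t0)))
    vals <- matrix(vals, nrow = length(t0))
    n <- ncol(vals)
    mu <- rowMeans(vals)
    sem <- if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(t0))
    curve[[id]] <- data.frame(scenario_id = id, time_h = t0, mean = mu,
                              sem = sem, n = n)
    endpoints[[id]] <- data.frame(
      scenario_id = id,
      replicate = vapply(grp, function(s) as.integer(s$replicate), 0L),
      endpoint = vals[nrow(vals), ])
  }
  curve <- do.call(rbind, curve); rownames(curve) <- NULL
  endpoints <- do.call(rbind, endpoints); rownames(endpoints) <- NULL
  ratios <- NULL
  if (!is.null(ratio_pairs)) {
    ep_mean <- tapply(endpoints$endpoint, endpoints$scenario_id, mean)
    ratios <- do.call(rbind, lapply(ratio_pairs, function(p) {
      if (!all(p %in% names(ep_mean))) {
        stop("ratio pair references unknown scenario: ",
             paste(p, collapse = " / "), call. = FALSE)
      }
      data.frame(numerator = p[1], denominator = p[2],
                 ratio = unname(ep_mean[p[1]] / ep_mean[p[2]]))
    }))
  }
  list(curve = curve, endpoints = endpoints, ratios = ratios)
}
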