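#' Read observation series from a tidy CSV file
#'
#' The tidy schema has columns `scenario_id, replicate, time_h, value, unit`
#' with one row per sample. Rows are grouped into one
#' [observation_series()] per `(scenario_id, replicate)`. All validation
#' problems (missing columns, non-numeric fields, duplicated times within a
#' series, mixed units) are collected and reported together with row
#' numbers.
#'
#' @param path CSV file path.
#' @param expected_unit optional unit label; if given, the file's unit must
#'   match.
#' @return A list of [observation_series()].
#' @export
read_timeseries_csv <- function(path, expected_unit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("scenario_id", "replicate", "time_h", "value", "unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  row_of <- function(i) i + 1L  # header line
  time_h <- suppressWarnings(as.numeric(df$time_h))
  value <- suppressWarnings(as.numeric(df$value))
  bad_t <- which(is.na(time_h) & nzchar(df$time_h))
  bad_v <- which(is.na(value) & nzchar(df$value))
  na_t <- which(is.na(time_h))
  na_v <- which(is.na(value))
  if (length(na_t)) {
    problems <- c(problems, paste0("non-numeric or empty time_h at row(s) ",
                                   paste(row_of(na_t), collapse = ", ")))
  }
  if (length(na_v)) {
    problems <- c(problems, paste0("non-numeric or empty value at row(s) ",
                                   paste(row_of(na_v), collapse = ", ")))
  }
  units <- unique(df$unit)
  if (length(units) > 1L) {
    problems <- c(problems, paste0("mixed units in one file: ",
                                   paste(units, collapse = ", ")))
  }
  if (!is.null(expected_unit) && length(units) == 1L &&
      units != expected_unit) {
    problems <- c(problems, paste0("unit '", units, "' does not match expected '",
                                   expected_unit, "'"))
  }
  key <- paste(df$scenario_id, df$replicate, df$time_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems,
                  paste0("duplicated (scenario, replicate, time) at row(s) ",
                         paste(row_of(dup), collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid time-series file '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df$time_h <- time_h; df$value <- value
  groups <- split(df, list(df$scenario_id, df$replicate), drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    observation_series(g$time_h, g$value, unit = g$unit[1],
                       replicate = g$replicate[1],
                       scenario_id = g$scenario_id[1])
  })
  ord <- order(vapply(out, function(s) paste(s$scenario_id, s$replicate), ""))
  unname(out[ord])
}

#' Write observation series to a tidy CSV file
#'
#' Inverse of [read_timeseries_csv()]: deterministic row order (scenario,
#' replicate, time), numbers rendered with 10 significant digits, one unit
#' per file.
#'
#' @param series list of [observation_series()] (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  if (inherits(series, "observation_series")) series <- list(series)
  header <- "scenario_id,replicate,time_h,value,unit"
  if (length(series) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  units <- unique(vapply(series, `[[`, "", "unit"))
  if (length(units) > 1L) {
    stop("units must be homogeneous per file, got: ",
         paste(units, collapse = ", "), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(scenario_id = as.character(s$scenario_id),
               replicate = as.character(s$replicate),
               time_h = s$times, value = s$values, unit = s$unit,
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$scenario_id, rows$replicate, rows$time_h), ]
  rows$time_h <- signif(rows$time_h, 10)
  rows$value <- signif(rows$value, 10)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit result as a one-row CSV table
#'
#' Layout mirrors how calibration results are tabulated per data series:
#' the four rates followed by the minimum objective value.
#'
#' @param fit a `fit_result` from [multistart_fit()] (or a list of them).
#' @param path output CSV path.
#' @param series_id identifier column value(s).
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path, series_id = "series1") {
  fits <- if (inherits(fit, "fit_result")) list(fit) else fit
  rows <- do.call(rbind, Map(function(f, id) {
    k <- unclass(f$params)
    data.frame(series_id = id, k_in = k[1], k_d = k[2], k_c = k[3],
               k_out = k[4], V_min = f$V_min,
               frac_within_tol = f$frac_within_tol,
               stringsAsFactors = FALSE)
  }, fits, series_id))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
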