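#' Two-phase (slow/rapid) piecewise-linear regression
#'
#' Cumulative penetration curves of cream formulations often show an initial
#' slow segment (release from the formulation and filling of the upper skin
#' layers) followed by a faster absorption segment. This fits a continuous
#' two-segment piecewise-linear model
#' `y = a + b1 * t + b2 * max(t - tau, 0)` by exhaustive search over
#' candidate breakpoints `tau` placed at interior observed sample times,
#' with ordinary least squares for each candidate; the candidate with the
#' smallest residual sum of squares wins (earliest such breakpoint on ties).
#' Candidates leaving fewer than 3 points on either side are skipped.
#'
#' @param data an [observation_series()] with at least 6 samples.
#' @return A list of class `two_phase_fit`: `breakpoint` (h), `slope_slow`
#'   (first-segment slope), `slope_rapid` (second-segment slope),
#'   `intercept_slow`, `intercept_rapid` (intercepts of the two lines in
#'   `y = intercept + slope * t` form), `rss`, `fitted`.
#' @examples
#' tt <- seq(0, 6, 0.5)
#' y <- ifelse(tt <= 3, tt, 3 + 3 * (tt - 3))
#' two_phase_regression(observation_series(tt, y))
#' @export
two_phase_regression <- function(data) {
  if (!inherits(data, "observation_series")) {
    stop("data must be an observation_series", call. = FALSE)
  }
  t <- data$times; y <- data$values
  if (length(t) < 6L) {
    stop("two_phase_regression needs at least 6 samples, got ", length(t),
         call. = FALSE)
  }
  best <- NULL
  for (tau in t[-c(1L, length(t))]) {
    if (sum(t <= tau) < 3L || sum(t >= tau) < 3L) next
    X <- cbind(1, t, pmax(t - tau, 0))
    co <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(co)) next
    fit <- drop(X %*% co)
    rss <- sum((y - fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(tau = tau, co = co, rss = rss, fitted = fit)
    }
  }
  if (is.null(best)) {
    stop("no admissible breakpoint (need >= 3 points on each side)",
         call. = FALSE)
  }
  a <- unname(best$co[1]); b1 <- unname(best$co[2]); b2 <- unname(best$co[3])
  structure(list(breakpoint = best$tau,
                 slope_slow = b1,
                 slope_rapid = b1 + b2,
                 intercept_slow = a,
                 intercept_rapid = a - b2 * best$tau,
                 rss = best$rss,
                 fitted = best$fitted),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat("<two_phase_fit> breakpoint ", format(x$breakpoint), " h; slopes ",
      format(signif(x$slope_slow, 5)), " -> ",
      format(signif(x$slope_rapid, 5)), " (RSS ",
      format(signif(x$rss, 4)), ")\n", sep = "")
  invisible(x)
}
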