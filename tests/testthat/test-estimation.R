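test_that("the normalized objective behaves as a relative residual norm", {
  ym <- observation_series(c(1, 2), c(3, 4))
  expect_equal(objective_value(ym, ym), 0)
  expect_equal(objective_value(ym, observation_series(c(1, 2), c(0, 0))), 1)
  expect_equal(objective_value(c(3, 4), c(0, 4)), 0.6)
  # scale invariance
  set.seed(2)
  a <- stats::runif(10); b <- stats::runif(10)
  expect_equal(objective_value(7.3 * a, 7.3 * b), objective_value(a, b))
  expect_error(objective_value(c(0, 0), c(1, 2)), "identically zero")
  expect_error(objective_value(c(1, 2, 3), c(1, 2)), "equal length")
})

test_that("a single fit started at the optimum stays there", {
  truth <- rate_parameters(1, 0.08, 0.32, 0.04)
  tt <- seq(0, 6, 0.5)
  data <- observe(simulate_closed_form(truth, times = tt))
  f <- single_fit(data, truth, fit_config(max_cycles = 3))
  expect_lt(f$V, 1e-8)
  expect_lt(rel_err(unclass(f$params), unclass(truth)), 1e-4)
  expect_true(f$converged)
})

test_that("errors from degenerate data propagate cleanly", {
  zero <- observation_series(seq(0, 6, 0.5), rep(0, 13))
  expect_error(single_fit(zero, rate_parameters(1, 1, 1, 1)),
               "identically zero")
  expect_error(multistart_fit(zero), "identically zero")
})

test_that("a small multistart recovers a noise-free truth exactly and
           deterministically", {
  truth <- rate_parameters(5, 0.08, 0.32, 0.04)
  tt <- seq(0, 6, 0.5)
  data <- observe(simulate_closed_form(truth, times = tt))

  fit1 <- multistart_fit(data, fit_config(n_starts = 6, seed = 1))
  expect_lt(fit1$V_min, 1e-8)
  expect_lt(rel_err(unclass(fit1$params), unclass(truth)), 1e-3)
  expect_equal(fit1$frac_within_tol, 1)

  # different seed, same best parameters
  fit2 <- multistart_fit(data, fit_config(n_starts = 6, seed = 99))
  expect_lt(rel_err(unclass(fit2$params), unclass(fit1$params)), 1e-6)

  # same seed twice is identical
  fit3 <- multistart_fit(data, fit_config(n_starts = 6, seed = 1))
  expect_identical(fit1$params, fit3$params)

  # best-so-far objective across starts is nonincreasing by construction
  running <- cummin(ifelse(is.na(fit1$per_start$V), Inf, fit1$per_start$V))
  expect_true(all(diff(running) <= 0))
})

test_that("a 1-start multistart equals the single fit from that start", {
  truth <- rate_parameters(2, 0.1, 0.4, 0.05)
  tt <- seq(0, 6, 0.5)
  data <- observe(simulate_closed_form(truth, times = tt))
  cfg <- fit_config(n_starts = 1, seed = 7)
  start <- withr::with_seed(cfg$seed, {
    10^stats::runif(4, log10(cfg$start_bounds[1]), log10(cfg$start_bounds[2]))
  })
  ms <- multistart_fit(data, cfg)
  sf <- single_fit(data, as_rate_parameters(start), cfg)
  expect_equal(ms$V_min, sf$V)
  expect_equal(unclass(ms$params), unclass(sf$params))
})

test_that("recovery reporting: empty, noise-free, and noise ordering", {
  truth <- rate_parameters(5, 0.08, 0.32, 0.04)
  tt <- seq(0, 6, 0.5)

  rep0 <- parameter_recovery_experiment(truth, tt, n_repeats = 0)
  expect_identical(nrow(rep0$errors), 0L)

  cfg <- fit_config(n_starts = 4)
  rep_nf <- parameter_recovery_experiment(truth, tt, noise_cv = 0,
                                          n_repeats = 2, seed = 5,
                                          config = cfg)
  expect_true(all(rep_nf$summary$median_abs_rel_error < 1e-3))

  # estimation degrades as noise grows: parameter error jumps once noise
  # enters, and the residual floor V_min tracks the noise level
  rep_lo <- parameter_recovery_experiment(truth, tt, noise_cv = 0.05,
                                          n_repeats = 3, seed = 5, config = cfg)
  rep_hi <- parameter_recovery_experiment(truth, tt, noise_cv = 0.10,
                                          n_repeats = 3, seed = 5, config = cfg)
  err <- function(r) stats::median(r$summary$median_abs_rel_error)
  expect_lt(err(rep_nf), err(rep_lo))
  expect_lt(err(rep_nf), err(rep_hi))
  expect_lt(stats::median(rep_nf$V_min), stats::median(rep_lo$V_min))
  expect_lt(stats::median(rep_lo$V_min), stats::median(rep_hi$V_min))
})

test_that("two-phase regression recovers a constructed breakpoint", {
  tt <- seq(0, 6, 0.5)
  y <- ifelse(tt <= 3, tt, 3 + 3 * (tt - 3))
  f <- two_phase_regression(observation_series(tt, y))
  expect_equal(f$breakpoint, 3)
  expect_equal(f$slope_slow, 1, tolerance = 1e-8)
  expect_equal(f$slope_rapid, 3, tolerance = 1e-8)
  expect_lt(f$rss, 1e-16)
  # continuity at the breakpoint
  left <- f$intercept_slow + f$slope_slow * f$breakpoint
  right <- f$intercept_rapid + f$slope_rapid * f$breakpoint
  expect_equal(left, right, tolerance = 1e-10)
})

test_that("two-phase regression degenerates gracefully on linear data", {
  tt <- seq(0, 6, 0.5)
  f <- two_phase_regression(observation_series(tt, 2.5 * tt + 1))
  expect_equal(f$slope_slow, f$slope_rapid, tolerance = 1e-8)
  expect_lt(f$rss, 1e-14)
})

test_that("two-phase regression refuses too-short series", {
  expect_error(two_phase_regression(observation_series(1:5, 1:5)),
               "at least 6")
})
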