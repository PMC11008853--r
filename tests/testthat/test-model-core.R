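test_that("the right-hand side matches the balance equations", {
  # only inflow active
  expect_equal(unname(compute_derivative(c(0, 0, 0), rate_parameters(1, 0, 0, 0))),
               c(1, 0, 0))
  # uniform state under pure diffusion has zero net flux
  expect_equal(unname(compute_derivative(c(1, 1, 1), rate_parameters(0, 1, 0, 0))),
               c(0, 0, 0))
  # hand substitution
  expect_equal(unname(compute_derivative(c(1, 2, 3), rate_parameters(0.5, 2, 1, 3))),
               c(1.5, -1, -9))
  expect_error(compute_derivative(c(1, NA, 3), rate_parameters(1, 1, 1, 1)),
               "finite")
  expect_error(rate_parameters(1, -0.1, 1, 1), "nonnegative")
  expect_error(rate_parameters(1, Inf, 1, 1), "finite")
})

test_that("system matrices encode the model and are Metzler/compartmental", {
  m0 <- system_matrices(rate_parameters(0, 0, 0, 0))
  expect_equal(unname(m0$A), matrix(0, 3, 3))
  expect_equal(m0$b, c(0, 0, 0))

  m1 <- system_matrices(rate_parameters(1, 1, 1, 1))
  expect_equal(unname(m1$A),
               matrix(c(-2, 1, 0, 2, -3, 1, 0, 2, -2), 3, 3, byrow = TRUE))
  expect_equal(m1$b, c(1, 0, 0))

  set.seed(11)
  ks <- draw_rates(5)
  for (i in seq_len(nrow(ks))) {
    m <- system_matrices(ks[i, ])
    offdiag <- m$A[row(m$A) != col(m$A)]
    expect_true(all(offdiag >= 0))
    for (j in 1:10) {
      x <- stats::runif(3, 0, 5)
      expect_equal(unname(compute_derivative(x, ks[i, ])),
                   unname(drop(m$A %*% x) + m$b), tolerance = 1e-12)
    }
  }
})

test_that("closed-form simulation is exact in degenerate and regular cases", {
  # all rates zero: constant trajectory
  tr <- simulate_closed_form(rate_parameters(0, 0, 0, 0), x0 = c(1, 2, 3),
                             times = c(0, 1, 2, 5))
  expect_equal(tr$states, matrix(rep(c(1, 2, 3), each = 4), ncol = 3),
               ignore_attr = TRUE)
  # long-time limit is the steady state
  p <- rate_parameters(1, 1, 1, 1)
  tr <- simulate_closed_form(p, times = c(0, 50))
  expect_equal(unname(tr$states[2, ]), unname(steady_state(p)), tolerance = 1e-8)
})

test_that("closed-form and numerical integration agree to 1e-8", {
  set.seed(42)
  ks <- draw_rates(20)
  tt <- seq(0, 6, 0.5)
  for (i in seq_len(nrow(ks))) {
    a <- simulate_closed_form(ks[i, ], times = tt)
    b <- simulate_numeric(ks[i, ], times = tt)
    scale <- max(abs(a$states), 1e-12)
    expect_lt(max(abs(a$states - b$states)) / scale, 1e-8)
  }
})

test_that("simulation preserves nonnegativity and monotone receptor filling", {
  set.seed(7)
  ks <- draw_rates(50)
  tt <- seq(0, 6, 0.5)
  for (i in seq_len(nrow(ks))) {
    tr <- simulate_closed_form(ks[i, ], times = tt)
    expect_gt(min(tr$states), -1e-9)
    # with a drug-free start the receptor concentration is nondecreasing
    expect_true(all(diff(tr$states[, 3]) >= -1e-9 * max(tr$states)))
  }
  # zero input from a drug-free start stays identically zero
  z <- simulate_numeric(rate_parameters(0, 1, 1, 1), times = tt)
  expect_equal(max(abs(z$states)), 0, tolerance = 1e-12)
})

test_that("mass balance and linearity in the inflow hold algebraically", {
  set.seed(3)
  ks <- draw_rates(20)
  for (i in seq_len(nrow(ks))) {
    x <- stats::runif(3, 0, 10)
    d <- compute_derivative(x, ks[i, ])
    expect_equal(sum(d), unname(ks[i, "k_in"] - ks[i, "k_out"] * x[3]),
                 tolerance = 1e-10)
  }
  # doubling k_in doubles the trajectory from a drug-free start
  k <- rate_parameters(0.7, 0.3, 0.6, 0.2)
  k2 <- rate_parameters(1.4, 0.3, 0.6, 0.2)
  tt <- seq(0, 8, 1)
  expect_equal(2 * simulate_closed_form(k, times = tt)$states,
               simulate_closed_form(k2, times = tt)$states,
               tolerance = 1e-12)
})

test_that("the system is stable for strictly positive rates", {
  set.seed(19)
  ks <- draw_rates(20)
  tt <- c(0, 200)
  for (i in seq_len(nrow(ks))) {
    m <- system_matrices(ks[i, ])
    expect_true(all(Re(eigen(m$A, only.values = TRUE)$values) < 0))
  }
  # and the trajectory converges to the steady state
  k <- rate_parameters(2, 0.5, 0.3, 0.8)
  tr <- simulate_closed_form(k, x0 = c(5, 0, 1), times = c(0, 300))
  expect_equal(unname(tr$states[2, ]), unname(steady_state(k)), tolerance = 1e-8)
})

test_that("steady state solves the balance and pins x3 = k_in/k_out", {
  expect_equal(unname(steady_state(rate_parameters(0, 1, 1, 1))), c(0, 0, 0))
  expect_equal(steady_state(rate_parameters(2, 0.9, 1.7, 4))[["x3"]], 0.5)
  expect_equal(unname(steady_state(rate_parameters(1, 1, 1, 1))), c(1, 1, 1))
  expect_error(steady_state(rate_parameters(1, 1, 1, 0)), "k_out")
  expect_error(steady_state(rate_parameters(1, 0, 0, 1)), "k_d \\+ k_c")
})

test_that("observation extracts y = x3 or the cumulative outflow", {
  k <- rate_parameters(1, 0.4, 0.3, 0.6)
  tt <- seq(0, 6, 0.5)
  tr <- simulate_closed_form(k, times = tt)
  y <- observe(tr, "direct")
  expect_identical(y$values, tr$states[, 3])

  # constant receptor concentration (start at equilibrium): M(T) = k_out*c*T
  xss <- steady_state(k)
  tr_eq <- simulate_closed_form(k, x0 = unname(xss), times = tt)
  m <- observe(tr_eq, "cumulative_outflow")
  expect_equal(m$values, k[["k_out"]] * xss[["x3"]] * tt, tolerance = 1e-8)

  # nondecreasing for nonnegative receptor series
  set.seed(5)
  for (i in 1:5) {
    tr2 <- simulate_closed_form(draw_rates(1)[1, ], times = tt)
    expect_true(all(diff(observe(tr2, "cumulative_outflow")$values) >= 0))
  }
  expect_error(observe(tr, "nonsense"))
})

test_that("observation series validates its inputs", {
  expect_error(observation_series(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(observation_series(c(0, 1), c(1, NA)), "finite")
  expect_error(observation_series(c(0, 1), c(1, 2, 3)), "equal length")
})
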