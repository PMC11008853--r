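#' System matrices of the three-compartment transport model
#'
#' The model is the linear time-invariant system `x'(t) = A x(t) + b` with
#' three compartments. Compartment 1 receives the constant donor inflow
#' `k_in`; neighbouring compartments exchange material diffusively at rate
#' `k_d` (both directions) and convectively at rate `k_c` (downward only);
#' the receptor compartment 3 is washed out at rate `k_out`:
#'
#' \deqn{x_1' = k_{in} + k_d x_2 - (k_d + k_c) x_1}
#' \deqn{x_2' = (k_d + k_c) x_1 + k_d x_3 - (2 k_d + k_c) x_2}
#' \deqn{x_3' = (k_d + k_c) x_2 - (k_d + k_{out}) x_3}
#'
#' `A` is a Metzler (off-diagonal nonnegative) compartmental matrix and
#' `b = (k_in, 0, 0)`.
#'
#' @param params a [rate_parameters()] object (or coercible vector).
#' @return A list with elements `A` (3 x 3 matrix) and `b` (length-3 vector).
#' @examples
#' system_matrices(rate_parameters(1, 1, 1, 1))
#' @export
system_matrices <- function(params) {
  params <- as_rate_parameters(params)
  k_in <- params[["k_in"]]; k_d <- params[["k_d"]]
  k_c <- params[["k_c"]]; k_out <- params[["k_out"]]
  s <- k_d + k_c
  A <- matrix(c(-s,    k_d,          0,
                 s, -(2 * k_d + k_c), k_d,
                 0,    s,         -(k_d + k_out)),
              nrow = 3, byrow = TRUE)
  dimnames(A) <- list(paste0("x", 1:3), paste0("x", 1:3))
  list(A = A, b = c(k_in, 0, 0))
}

#' Time derivative of the compartment concentrations
#'
#' Evaluates the right-hand side of the three-compartment model at one state.
#'
#' @param state numeric vector `(x1, x2, x3)` of compartment concentrations.
#' @param params a [rate_parameters()] object (or coercible vector).
#' @return Numeric vector `(dx1, dx2, dx3)`.
#' @examples
#' compute_derivative(c(1, 2, 3), rate_parameters(0.5, 2, 1, 3))
#' @export
compute_derivative <- function(state, params) {
  params <- as_rate_parameters(params)
  state <- as.numeric(state)
  if (length(state) != 3L || any(!is.finite(state))) {
    stop("state must be 3 finite concentrations (x1, x2, x3)", call. = FALSE)
  }
  m <- system_matrices(params)
  drop(m$A %*% state) + m$b
}

# internal trajectory constructor
new_trajectory <- function(times, states, params) {
  colnames(states) <- paste0("x", 1:3)
  structure(list(times = times, states = states, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points over [",
      format(min(x$times)), ", ", format(max(x$times)), "] h\n", sep = "")
  cat("final state:", paste(signif(x$states[nrow(x$states), ], 6),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Exact simulation of the compartment model
#'
#' Solves the linear system `x' = A x + b` exactly (up to floating point) on
#' an arbitrary strictly increasing time grid. The constant input is folded
#' into an augmented 4 x 4 system `z' = M z`, `z = (x, 1)`,
#' `M = [[A, b], [0, 0]]`, and the state is propagated between grid points
#' with the matrix exponential `exp(M dt)`. The augmented form needs no
#' inversion of `A`, so singular `A` (e.g. `k_out = 0`, or all rates zero)
#' is handled by the same exact path rather than a special case.
#'
#' @param params a [rate_parameters()] object (or coercible vector).
#' @param x0 initial concentrations at `t = 0`, default `c(0, 0, 0)`
#'   (drug-free skin and receptor).
#' @param times strictly increasing grid in hours; need not contain 0.
#' @return A `trajectory` object: list with `times`, a matrix `states`
#'   (one row per time point, columns `x1..x3`) and `params`.
#' @examples
#' tr <- simulate_closed_form(rate_parameters(1, 1, 1, 1), times = seq(0, 10, 0.5))
#' @export
simulate_closed_form <- function(params, x0 = c(0, 0, 0), times) {
  params <- as_rate_parameters(params)
  assert_time_grid(times)
  x0 <- as.numeric(x0)
  if (length(x0) != 3L || any(!is.finite(x0))) {
    stop("x0 must be 3 finite values", call. = FALSE)
  }
  m <- system_matrices(params)
  M <- rbind(cbind(m$A, m$b), 0)
  z <- c(x0, 1)
  states <- matrix(0, nrow = length(times), ncol = 3)
  tprev <- 0
  E <- NULL; last_dt <- -1
  for (i in seq_along(times)) {
    dt <- times[i] - tprev
    if (dt > 0) {
      if (dt != last_dt) {          # uniform grids reuse one exponential
        E <- as.matrix(Matrix::expm(M * dt))
        last_dt <- dt
      }
      z <- E %*% z
    }
    states[i, ] <- z[1:3]
    tprev <- times[i]
  }
  new_trajectory(times, states, params)
}

#' Numerical simulation of the compartment model
#'
#' Integrates the model with `deSolve::lsoda()`. Used as an independent
#' cross-check of [simulate_closed_form()]; both should agree to near
#' machine precision for this small linear system.
#'
#' @inheritParams simulate_closed_form
#' @param rtol,atol integrator tolerances (default `1e-10` / `1e-12`).
#' @return A `trajectory` object.
#' @export
simulate_numeric <- function(params, x0 = c(0, 0, 0), times,
                             rtol = 1e-10, atol = 1e-12) {
  params <- as_rate_parameters(params)
  assert_time_grid(times)
  x0 <- as.numeric(x0)
  if (length(x0) != 3L || any(!is.finite(x0))) {
    stop("x0 must be 3 finite values", call. = FALSE)
  }
  m <- system_matrices(params)
  rhs <- function(t, x, p) list(drop(m$A %*% x) + m$b)
  tt <- times
  prepend0 <- tt[1] > 0
  if (prepend0) tt <- c(0, tt)
  sol <- deSolve::ode(y = x0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  diag_attr <- attributes(sol)$istate
  if (!is.null(diag_attr) && diag_attr[1] < 0) {
    stop("lsoda failed with istate = ", diag_attr[1], call. = FALSE)
  }
  states <- unname(sol[, 2:4, drop = FALSE])
  if (prepend0) states <- states[-1, , drop = FALSE]
  new_trajectory(times, states, params)
}

#' Steady state of the compartment model
#'
#' Solves `A x + b = 0`. Summing the three balance equations shows
#' `d(x1+x2+x3)/dt = k_in - k_out * x3`, so the receptor concentration at
#' equilibrium is always `x3* = k_in / k_out`.
#'
#' @param params a [rate_parameters()] object with `k_out > 0` and
#'   `k_d + k_c > 0` (otherwise `A` is singular and no finite equilibrium
#'   exists for `k_in > 0`).
#' @return Named numeric vector `(x1, x2, x3)`.
#' @examples
#' steady_state(rate_parameters(2, 1, 1, 4))[["x3"]]  # = 0.5
#' @export
steady_state <- function(params) {
  params <- as_rate_parameters(params)
  if (params[["k_out"]] <= 0) {
    stop("steady_state requires k_out > 0 (receptor washout); got k_out = ",
         format(params[["k_out"]]), call. = FALSE)
  }
  if (params[["k_d"]] + params[["k_c"]] <= 0) {
    stop("steady_state requires k_d + k_c > 0 (inter-compartment transport); ",
         "got k_d = ", format(params[["k_d"]]),
         ", k_c = ", format(params[["k_c"]]), call. = FALSE)
  }
  m <- system_matrices(params)
  x <- drop(solve(m$A, -m$b))
  names(x) <- paste0("x", 1:3)
  x
}

#' Observation series container
#'
#' A measured or simulated observable on a sampling grid. The observable of
#' the chip experiments is the cumulative penetrated mass per diffusion area
#' (ug/cm2 or ng/cm2); simulated series use the same units as the data they
#' emulate.
#'
#' @param times sampling times in hours (strictly increasing).
#' @param values observable values, same length as `times`, finite.
#' @param unit unit label, e.g. `"ug/cm2"`.
#' @param replicate replicate identifier (integer or character).
#' @param scenario_id optional scenario identifier.
#' @return An object of class `observation_series` (a list).
#' @export
observation_series <- function(times, values, unit = "ug/cm2",
                               replicate = 1L, scenario_id = NA_character_) {
  assert_time_grid(times)
  values <- as.numeric(values)
  if (length(values) != length(times)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), values = values, unit = unit,
                 replicate = replicate, scenario_id = scenario_id),
            class = "observation_series")
}

#' @export
print.observation_series <- function(x, ...) {
  cat("<observation_series> ", x$scenario_id, " replicate ", x$replicate,
      ": ", length(x$times), " samples over [", format(min(x$times)), ", ",
      format(max(x$times)), "] h, unit ", x$unit, "\n", sep = "")
  invisible(x)
}

#' Extract the observable from a trajectory
#'
#' The measured quantity of the chip experiment is the receptor compartment:
#' `y = x3` (`mode = "direct"`, the default used throughout the analysis).
#' As an alternative bookkeeping view, `mode = "cumulative_outflow"` returns
#' the material carried away by the perfusion flow,
#' `M(t) = integral_0^t k_out x3(s) ds`, evaluated by the trapezoidal rule
#' on the trajectory grid (the grid should start at 0 for the integral to
#' start at the experiment start).
#'
#' @param trajectory a `trajectory` from [simulate_closed_form()] or
#'   [simulate_numeric()].
#' @param mode `"direct"` or `"cumulative_outflow"`.
#' @param unit,replicate,scenario_id passed to [observation_series()].
#' @return An [observation_series()].
#' @export
observe <- function(trajectory, mode = c("direct", "cumulative_outflow"),
                    unit = "ug/cm2", replicate = 1L,
                    scenario_id = NA_character_) {
  if (!inherits(trajectory, "trajectory")) {
    stop("trajectory must be a 'trajectory' object", call. = FALSE)
  }
  mode <- match.arg(mode)
  x3 <- trajectory$states[, 3]
  if (mode == "direct") {
    vals <- x3
  } else {
    k_out <- trajectory$params[["k_out"]]
    f <- k_out * x3
    tt <- trajectory$times
    n <- length(tt)
    if (n == 1L) {
      vals <- 0
    } else {
      incr <- diff(tt) * (f[-1] + f[-n]) / 2
      vals <- c(0, cumsum(incr))
    }
  }
  observation_series(trajectory$times, vals, unit = unit,
                     replicate = replicate, scenario_id = scenario_id)
}
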