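#' Transport rate parameters of the three-compartment skin model
#'
#' Bundles the four first-order transport rates that govern drug movement
#' from the donor formulation through two skin compartments into the
#' perfused receptor compartment:
#'
#' * `k_in`  -- constant inflow from the (undepleted) donor formulation into
#'   the uppermost compartment, in observable concentration units per hour;
#' * `k_d`   -- diffusive exchange rate between neighbouring compartments (1/h);
#' * `k_c`   -- convective (directed) transport rate (1/h);
#' * `k_out` -- first-order washout from the receptor compartment by the
#'   perfusion flow (1/h).
#'
#' All rates must be finite and nonnegative. Several operations (steady
#' state, identifiability analysis) additionally require strict positivity
#' and say so in their own documentation.
#'
#' @param k_in,k_d,k_c,k_out single finite nonnegative numbers.
#' @return An object of class `rate_parameters`: a named numeric vector with
#'   elements `k_in`, `k_d`, `k_c`, `k_out`.
#' @examples
#' rate_parameters(k_in = 1, k_d = 0.5, k_c = 0.2, k_out = 2)
#' @export
rate_parameters <- function(k_in, k_d, k_c, k_out) {
  k <- c(k_in = unname(k_in), k_d = unname(k_d), k_c = unname(k_c),
         k_out = unname(k_out))
  if (length(k) != 4L || !is.numeric(k)) {
    stop("all four rates must be single numeric values", call. = FALSE)
  }
  if (any(!is.finite(k))) {
    stop("rate parameters must be finite, got (",
         paste(format(k), collapse = ", "), ")", call. = FALSE)
  }
  if (any(k < 0)) {
    stop("rate parameters must be nonnegative, got (",
         paste(format(k), collapse = ", "), ")", call. = FALSE)
  }
  structure(k, class = "rate_parameters")
}

#' Coerce a plain vector to rate parameters
#'
#' @param x numeric vector of length 4 ordered `(k_in, k_d, k_c, k_out)`,
#'   or an existing `rate_parameters` object (returned unchanged).
#' @return A [rate_parameters()] object.
#' @export
as_rate_parameters <- function(x) {
  if (inherits(x, "rate_parameters")) return(x)
  x <- unname(as.numeric(x))
  if (length(x) != 4L) stop("expected 4 rates (k_in, k_d, k_c, k_out)", call. = FALSE)
  rate_parameters(x[1], x[2], x[3], x[4])
}

#' @export
print.rate_parameters <- function(x, digits = 6, ...) {
  cat("<rate_parameters>  (units: k_in in obs/h, others 1/h)\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

# internal: strictly positive check with a caller-supplied context message
assert_positive_rates <- function(params, what) {
  if (any(unclass(params) <= 0)) {
    bad <- names(params)[unclass(params) <= 0]
    stop(what, " requires strictly positive rates; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(params)
}

# internal: validate a time grid (strictly increasing, finite, nonnegative)
assert_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times))) {
    stop("times must be a finite numeric grid", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be nonnegative (hours)", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}
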