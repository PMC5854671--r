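# Stationary first-passage firing rate of the OU membrane potential and its
# derivative.  The integrand exp(x^2)(1 + erf(x)) equals erfcx(-x), which is
# evaluated without forming exp(x^2) explicitly; exp(x^2) alone overflows for
# x > ~26.6, at which point the rate has long underflowed to zero.

.siegert_integrand <- function(x) pracma::erfcx(-x)

# exp(x^2) overflows beyond sqrt(log(.Machine$double.xmax)) ~ 26.64; a little
# margin keeps the quadrature clear of Inf while the rate there is < 1e-290 Hz
.SIEGERT_XMAX <- 26

.siegert_integral <- function(params, sigma) {
  stats::integrate(.siegert_integrand, params$u_reset / sigma,
                   params$theta / sigma, rel.tol = 1e-10,
                   abs.tol = 0)$value
}

.check_sigma <- function(params, sigma) {
  stopifnot(inherits(params, "neuron_params"))
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("'sigma' must be positive and finite")
  if (params$theta <= params$u_reset)
    stop("degenerate neuron: 'theta' must exceed 'u_reset'")
  invisible(TRUE)
}

#' Stationary firing rate of the balanced LIF neuron
#'
#' Inverse of the expected first-passage time of the Ornstein-Uhlenbeck
#' membrane potential from reset to threshold:
#' `r(sigma) = 1 / (tau * sqrt(pi) * integral_{u_reset/sigma}^{theta/sigma}
#' exp(x^2) (1 + erf(x)) dx)`.
#' The integrand is evaluated through the scaled complementary error
#' function, so the map stays accurate deep into the low-noise regime; once
#' the threshold exceeds the noise scale by more than a factor ~26 the rate
#' underflows double precision and 0 is returned (the vanishing-noise limit).
#'
#' @param params A [neuron_params()].
#' @param sigma Fluctuation scale of the input in mV (> 0); may be a vector.
#'
#' @return Firing rate(s) in Hz.
#' @examples
#' p <- neuron_params()
#' siegert_rate(p, 13.675)   # ~10 Hz, the standard operating point
#' @seealso [sigma_for_rate()], [siegert_rate_deriv()]
#' @export
siegert_rate <- function(params, sigma) {
  .check_sigma(params, sigma)
  vapply(sigma, function(s) {
    if (params$theta / s > .SIEGERT_XMAX) return(0)
    1 / (params$tau * sqrt(pi) * .siegert_integral(params, s))
  }, numeric(1))
}

#' Derivative of the firing rate with respect to the input fluctuation scale
#'
#' `d r / d sigma`, obtained by differentiating the first-passage integral at
#' its endpoints (Leibniz rule), so the value is exact up to quadrature
#' tolerance (relative error < 1e-8, well inside the documented 1e-4).
#'
#' @inheritParams siegert_rate
#' @return Derivative(s) in Hz/mV; strictly positive wherever the rate is
#'   representable (the rate map is increasing in sigma).
#' @examples
#' siegert_rate_deriv(neuron_params(), 13.675)
#' @export
siegert_rate_deriv <- function(params, sigma) {
  .check_sigma(params, sigma)
  vapply(sigma, function(s) {
    if (params$theta / s > .SIEGERT_XMAX) return(0)
    I <- .siegert_integral(params, s)
    r <- 1 / (params$tau * sqrt(pi) * I)
    num <- params$theta * .siegert_integrand(params$theta / s) -
      params$u_reset * .siegert_integrand(params$u_reset / s)
    r * num / (s^2 * I)
  }, numeric(1))
}

#' Input scale that produces a target firing rate
#'
#' Inverts the (strictly increasing) rate map [siegert_rate()] by bracketed
#' root finding, e.g. to place a neuron at a 10 Hz operating point.
#'
#' @inheritParams siegert_rate
#' @param target_rate Desired firing rate in Hz (> 0).
#' @param interval Initial search interval for sigma in mV; expanded
#'   geometrically if it does not bracket the target.
#'
#' @return Sigma in mV with `siegert_rate(params, sigma)` within
#'   `1e-6 * target_rate` of the target.
#' @examples
#' p <- neuron_params()
#' s <- sigma_for_rate(p, 10)
#' siegert_rate(p, s)
#' @export
sigma_for_rate <- function(params, target_rate,
                           interval = c(params$theta / 20, 20 * params$theta)) {
  stopifnot(inherits(params, "neuron_params"),
            is.numeric(target_rate), length(target_rate) == 1L,
            is.finite(target_rate))
  if (target_rate <= 0) stop("'target_rate' must be positive")
  f <- function(s) siegert_rate(params, s) - target_rate
  lo <- interval[1]; hi <- interval[2]
  for (i in 1:60) {
    if (f(lo) < 0) break
    lo <- lo / 2
  }
  for (i in 1:60) {
    if (f(hi) > 0) break
    hi <- hi * 2
    if (!is.finite(f(hi))) break
  }
  if (!(f(lo) < 0 && f(hi) > 0))
    stop(sprintf("target rate %g Hz not bracketable in sigma range [%g, %g] mV",
                 target_rate, lo, hi))
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5 * lo)$root
  achieved <- siegert_rate(params, root)
  if (abs(achieved - target_rate) > 1e-6 * target_rate)
    stop(sprintf("root polishing failed: achieved %g Hz for target %g Hz",
                 achieved, target_rate))
  root
}

#' Fast interpolated rate map
#'
#' Builds a monotone spline of `log r(sigma)` on a sigma grid and returns a
#' vectorized function approximating [siegert_rate()].  Used in the learning
#' protocol, where the rate map is evaluated tens of thousands of times;
#' interpolation error is below 1e-6 relative on the tabulated range.
#' Below `theta / 6` the rate is astronomically small (< 1e-13 Hz) and the
#' interpolator returns 0; above the grid it falls back to quadrature.
#'
#' @inheritParams siegert_rate
#' @param sigma_max Upper end of the tabulated sigma range in mV.
#' @param n Number of grid points.
#'
#' @return A function `f(sigma)` returning rates in Hz.
#' @examples
#' rf <- siegert_rate_fun(neuron_params())
#' rf(c(5, 13.675, 20))
#' @export
siegert_rate_fun <- function(params, sigma_max = 6 * params$theta, n = 600) {
  stopifnot(inherits(params, "neuron_params"))
  sig_lo <- params$theta / 6
  grid <- exp(seq(log(sig_lo), log(sigma_max), length.out = n))
  logr <- log(siegert_rate(params, grid))
  sf <- stats::splinefun(grid, logr, method = "hyman")
  function(sigma) {
    out <- numeric(length(sigma))
    if (any(sigma < 0)) stop("'sigma' must be non-negative")
    inside <- sigma >= sig_lo & sigma <= sigma_max
    out[inside] <- exp(sf(sigma[inside]))
    high <- sigma > sigma_max
    if (any(high)) out[high] <- siegert_rate(params, sigma[high])
    out
  }
}
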