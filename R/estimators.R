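#' Maximum-likelihood rate estimate from a spike train
#'
#' For a Poisson spike train the spike count divided by the observation
#' window, `n / T`, is the maximum-likelihood (and minimum-variance
#' unbiased) estimator of the rate; the spike times themselves carry no
#' additional information.
#'
#' @param train A [spike_train()].
#' @return Estimated rate in Hz.
#' @examples
#' estimate_rate_spikes(spike_train(seq(0.05, 0.45, 0.1), 0.5))  # 10 Hz
#' @export
estimate_rate_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times) / train$duration
}

#' Variance of the spike-count rate estimator
#'
#' `Var = r / T`: the Fisher information about the rate in a Poisson spike
#' train grows linearly in the observation time only.
#'
#' @param rate True rate in Hz.
#' @param duration Observation window T in seconds (> 0).
#' @return Variance in Hz^2.
#' @examples
#' spike_estimator_variance(10, 0.5)   # 20 Hz^2
#' @export
spike_estimator_variance <- function(rate, duration) {
  stopifnot(is.numeric(rate), is.numeric(duration), all(duration > 0))
  rate / duration
}

#' Maximum-likelihood estimate of the input scale from a voltage trace
#'
#' Closed-form MLE of sigma from equidistant samples of the free OU
#' membrane potential:
#' `sigma_hat = sqrt( 2 * sum (u_{i+1} - u_i e^{-eps/tau})^2 /
#'                    (n (1 - e^{-2 eps/tau})) )`.
#' The squared estimator is unbiased and `n sigma_hat^2 / sigma^2` is
#' chi-squared with `n` degrees of freedom, so
#' `Var(sigma_hat) ~ sigma^2 eps / (2 T)` for large `n`.
#'
#' @param trace A [membrane_trace()].
#' @param params A [neuron_params()] (supplies `tau`).
#' @return Estimated sigma in mV (>= 0).
#' @examples
#' sim <- simulate_oup(neuron_params(), 14, duration = 10, epsilon = 1e-3,
#'                     seed = 1)
#' estimate_sigma_voltage(sim$trace, neuron_params())
#' @export
estimate_sigma_voltage <- function(trace, params) {
  stopifnot(inherits(trace, "membrane_trace"), inherits(params, "neuron_params"))
  a <- exp(-trace$epsilon / params$tau)
  u <- trace$samples
  n <- length(u) - 1L
  d <- u[-1L] - a * u[-length(u)]
  sqrt(2 * sum(d^2) / (n * (1 - a^2)))
}

#' Maximum-likelihood rate estimate from a voltage trace
#'
#' By the invariance of maximum likelihood, `r(sigma_hat)` with `sigma_hat`
#' from [estimate_sigma_voltage()] is an optimal rate estimator based on the
#' membrane potential.  By default, estimates below `params$rate_floor` are
#' rounded down to 0 Hz; pass `apply_floor = FALSE` to obtain the raw value
#' (the learning rules use the raw estimate).
#'
#' @inheritParams estimate_sigma_voltage
#' @param apply_floor Logical; round rates below `params$rate_floor` to 0.
#' @return Estimated rate in Hz.
#' @examples
#' tr <- membrane_trace(rep(0, 10), 1e-3)
#' estimate_rate_voltage(tr, neuron_params())   # 0
#' @export
estimate_rate_voltage <- function(trace, params, apply_floor = TRUE) {
  sig <- estimate_sigma_voltage(trace, params)
  r <- if (sig <= 0) 0 else siegert_rate(params, sig)
  if (apply_floor && r < params$rate_floor) 0 else r
}

#' Variance of the voltage-based rate estimator (balanced input)
#'
#' Delta-method variance `sigma^2 eps / (2 T) * (dr/dsigma)^2`: the Fisher
#' information about the rate in the membrane potential grows with the
#' observation time *and* the sampling rate `1/eps`.
#'
#' @param params A [neuron_params()].
#' @param sigma Input scale in mV.
#' @param epsilon Sampling interval in seconds.
#' @param duration Observation window T in seconds.
#' @return Variance in Hz^2.
#' @examples
#' voltage_estimator_variance(neuron_params(), 13.675, 1e-3, 0.01)
#' @export
voltage_estimator_variance <- function(params, sigma, epsilon, duration) {
  stopifnot(epsilon > 0, duration > 0)
  sigma^2 * epsilon / (2 * duration) *
    siegert_rate_deriv(params, sigma)^2
}

#' Variance of the voltage-based rate estimator without balance
#'
#' When excitation and inhibition do not cancel, the rate depends on the
#' mean depolarization mu as well as on sigma, and the estimator variance
#' gains a term that decreases only with the observation time and the
#' membrane time constant:
#' `Var = sigma^2 eps/(2T) (dr/dsigma)^2 + sigma^2 tau/T (dr/dmu)^2`.
#' The second term is independent of the sampling rate, which is why the
#' loosely balanced state is required for fast voltage-based decoding.
#'
#' @inheritParams voltage_estimator_variance
#' @param mu Mean depolarization in mV (enters only through `dr_dmu`).
#' @param dr_dsigma Partial derivative of the rate in sigma (Hz/mV).
#' @param dr_dmu Partial derivative of the rate in mu (Hz/mV).
#' @return Variance in Hz^2.
#' @examples
#' p <- neuron_params()
#' voltage_estimator_variance_unbalanced(p, 13.675, 0, 1e-3, 0.01,
#'                                       dr_dsigma = 1.78, dr_dmu = 0)
#' @export
voltage_estimator_variance_unbalanced <- function(params, sigma, mu, epsilon,
                                                  duration, dr_dsigma,
                                                  dr_dmu) {
  stopifnot(epsilon > 0, duration > 0, sigma > 0)
  sigma^2 * epsilon / (2 * duration) * dr_dsigma^2 +
    sigma^2 * params$tau / duration * dr_dmu^2
}

#' Spike-vs-voltage time-improvement factor
#'
#' Ratio `T_spike / T_voltage` of the observation times needed to extract
#' the same amount of rate information from spikes and from voltage
#' samples: `2 r / (sigma^2 eps (dr/dsigma)^2)`, with sigma placed at the
#' operating point `sigma_for_rate(rate)`.  Identically equal to the ratio
#' of the two estimator variances at any common window, and independent of
#' the plasticity rule it propagates into.
#'
#' @param params A [neuron_params()].
#' @param rate Firing rate of the neuron in Hz (> 0).
#' @param epsilon Sampling interval in seconds (> 0).
#' @return Dimensionless improvement factor.
#' @examples
#' time_improvement_factor(neuron_params(), 10, 1e-3)   # > 10
#' @export
time_improvement_factor <- function(params, rate, epsilon) {
  stopifnot(rate > 0, epsilon > 0)
  sigma <- sigma_for_rate(params, rate)
  2 * rate / (sigma^2 * epsilon * siegert_rate_deriv(params, sigma)^2)
}

#' Coverage probability of the spike-count rate estimator
#'
#' Probability that `n/T` falls within `accuracy` of the true rate, either
#' from the exact Poisson mass function or from the Gaussian approximation
#' `N(r, r/T)`.
#'
#' @param rate True rate in Hz.
#' @param duration Observation window T in seconds.
#' @param accuracy Half-width of the tolerated error band in Hz.
#' @param method `"exact"` (Poisson) or `"gaussian"`.
#' @return Coverage probability in `[0, 1]`.
#' @examples
#' spike_coverage(10, 0.5, 5)              # ~0.742
#' spike_coverage(10, 0.5, 5, "gaussian")
#' @export
spike_coverage <- function(rate, duration, accuracy,
                           method = c("exact", "gaussian")) {
  method <- match.arg(method)
  stopifnot(rate > 0, duration > 0, accuracy > 0)
  if (method == "exact") {
    lambda <- rate * duration
    lo <- ceiling((rate - accuracy) * duration)
    hi <- floor((rate + accuracy) * duration)
    if (hi < lo) return(0)
    stats::ppois(hi, lambda) - if (lo > 0) stats::ppois(lo - 1, lambda) else 0
  } else {
    sdv <- sqrt(rate / duration)
    stats::pnorm(accuracy / sdv) - stats::pnorm(-accuracy / sdv)
  }
}

#' Coverage probability of the voltage-based rate estimator
#'
#' Gaussian delta-method coverage `P(|r(sigma_hat) - r| <= accuracy)` using
#' the variance of [voltage_estimator_variance()].
#'
#' @inheritParams spike_coverage
#' @param params A [neuron_params()].
#' @param epsilon Sampling interval in seconds.
#' @return Coverage probability in `[0, 1]`.
#' @examples
#' voltage_coverage(neuron_params(), 10, 1e-3, 0.0128, 5)
#' @export
voltage_coverage <- function(params, rate, epsilon, duration, accuracy) {
  sigma <- sigma_for_rate(params, rate)
  sdv <- sqrt(voltage_estimator_variance(params, sigma, epsilon, duration))
  stats::pnorm(accuracy / sdv) - stats::pnorm(-accuracy / sdv)
}

#' Minimal observation window for a target estimation confidence
#'
#' Smallest window T at which the estimator attains `P(|r_hat - r| <=
#' accuracy) >= confidence`.  For the voltage estimator the Gaussian
#' delta-method coverage is monotone in T and the bound is closed-form:
#' `T = sigma^2 eps (dr/dsigma)^2 z^2 / (2 accuracy^2)` with
#' `z = qnorm((1 + confidence) / 2)`.  For the spike estimator the exact
#' Poisson coverage is non-monotone in T because the admissible spike-count
#' set changes discretely, so the smallest qualifying T on a grid is
#' reported alongside the Gaussian closed form.
#'
#' @param params A [neuron_params()].
#' @param rate True rate in Hz.
#' @param epsilon Sampling interval in seconds (voltage estimator).
#' @param accuracy Half-width of the tolerated error band in Hz.
#' @param confidence Required coverage probability.
#' @return For `min_duration_voltage`, the minimal T in seconds.  For
#'   `min_duration_spikes`, a list with the Gaussian closed form
#'   (`gaussian`) and the smallest grid point achieving exact Poisson
#'   coverage (`exact`).
#' @examples
#' min_duration_voltage(neuron_params(), 10, 1e-3)   # ~0.0127 s
#' min_duration_spikes(10)$gaussian                  # ~0.43 s
#' @export
min_duration_voltage <- function(params, rate, epsilon, accuracy = 5,
                                 confidence = 0.7) {
  stopifnot(rate > 0, epsilon > 0, accuracy > 0,
            confidence > 0, confidence < 1)
  sigma <- sigma_for_rate(params, rate)
  z <- stats::qnorm((1 + confidence) / 2)
  sigma^2 * epsilon * siegert_rate_deriv(params, sigma)^2 * z^2 /
    (2 * accuracy^2)
}

#' @rdname min_duration_voltage
#' @param grid Durations (s) scanned for the exact Poisson solution.
#' @export
min_duration_spikes <- function(rate, accuracy = 5, confidence = 0.7,
                                grid = seq(0.01, 5, by = 0.01)) {
  stopifnot(rate > 0, accuracy > 0, confidence > 0, confidence < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  gaussian <- rate * z^2 / accuracy^2
  cov <- vapply(grid, function(T) spike_coverage(rate, T, accuracy),
                numeric(1))
  ok <- which(cov >= confidence)
  exact <- if (length(ok)) grid[ok[1]] else NA_real_
  list(gaussian = gaussian, exact = exact)
}
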