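#' Rate-based plasticity rule
#'
#' A rate rule maps presynaptic and postsynaptic rates (and, for rules with
#' a sliding threshold, a reference rate) to a synaptic weight change per
#' stimulus presentation, `Delta_w = f(r_pre, r_post, r_bar)`.  The partial
#' derivative in the postsynaptic rate is carried along because the
#' variance of any spike- or voltage-based realization is proportional to
#' its square.
#'
#' @param f Function `(r_pre, r_post, r_bar)` returning the weight change
#'   (mV per presentation).
#' @param df_drpost Function with the same signature returning
#'   `d f / d r_post`.
#' @param name Optional label.
#' @return An object of class `"rate_rule"`.
#' @seealso [bcm_rule()], [linear_rule()]
#' @export
rate_rule <- function(f, df_drpost, name = "rate rule") {
  stopifnot(is.function(f), is.function(df_drpost))
  structure(list(f = f, df_drpost = df_drpost, name = name),
            class = "rate_rule")
}

#' @export
print.rate_rule <- function(x, ...) {
  cat("Rate-based plasticity rule:", x$name, "\n")
  invisible(x)
}

#' The BCM rule as a rate rule
#'
#' `f = eta * r_pre * (r_post^2 - r_bar * r_post)`: depression below the
#' sliding threshold `r_bar`, potentiation above it, gated by presynaptic
#' activity.
#'
#' @param eta Learning step size (> 0, dimensionless).
#' @return A [rate_rule()].
#' @examples
#' rule <- bcm_rule(1e-6)
#' rule$f(10, 10, 5)    # 5e-4
#' @export
bcm_rule <- function(eta = 1e-6) {
  stopifnot(eta > 0)
  rate_rule(
    f = function(r_pre, r_post, r_bar) eta * r_pre * (r_post^2 - r_bar * r_post),
    df_drpost = function(r_pre, r_post, r_bar) eta * r_pre * (2 * r_post - r_bar),
    name = sprintf("BCM (eta = %g)", eta)
  )
}

#' A linear test rule
#'
#' `f = scale * r_pre * r_post`, a plain Hebbian rule used to check that
#' the SDP/VDP variance ratio does not depend on the rule.
#'
#' @param scale Multiplier.
#' @return A [rate_rule()].
#' @export
linear_rule <- function(scale = 1) {
  rate_rule(
    f = function(r_pre, r_post, r_bar) scale * r_pre * r_post,
    df_drpost = function(r_pre, r_post, r_bar) scale * r_pre + 0 * r_post,
    name = sprintf("linear Hebb (scale = %g)", scale)
  )
}

#' BCM plasticity state
#'
#' Sliding threshold plus hyperparameters of the BCM rule.  The sliding
#' threshold relaxes towards the recent average of the *squared*
#' postsynaptic rate, so at a stationary rate r it converges to r^2.
#' `tau_bcm` counts protocol rounds (stimulus presentations), not seconds.
#'
#' @param r_bar_post Initial sliding threshold (Hz-scale, >= 0).
#' @param eta Learning step size (>= 0; 0 freezes learning).
#' @param tau_bcm Threshold time constant in rounds (> 0).
#' @return An object of class `"bcm_state"`.
#' @examples
#' bcm_state()
#' @export
bcm_state <- function(r_bar_post = 5, eta = 1e-6, tau_bcm = 1000) {
  stopifnot(r_bar_post >= 0, eta >= 0, tau_bcm > 0)
  structure(list(r_bar_post = r_bar_post, eta = eta, tau_bcm = tau_bcm),
            class = "bcm_state")
}

#' @export
print.bcm_state <- function(x, ...) {
  cat(sprintf("BCM state: r_bar = %g, eta = %g, tau_bcm = %g rounds\n",
              x$r_bar_post, x$eta, x$tau_bcm))
  invisible(x)
}

#' BCM weight change at known rates
#'
#' The idealized (noise-free) BCM weight change
#' `eta * r_pre * (r_post^2 - r_bar * r_post)` for one presentation.
#'
#' @param r_pre,r_post Presynaptic and postsynaptic rates in Hz (>= 0).
#' @param state A [bcm_state()].
#' @return Weight change in mV.
#' @examples
#' bcm_delta_w(10, 10, bcm_state(r_bar_post = 5, eta = 1e-6))  # 5e-4
#' @export
bcm_delta_w <- function(r_pre, r_post, state) {
  stopifnot(inherits(state, "bcm_state"), all(r_pre >= 0), all(r_post >= 0))
  state$eta * r_pre * (r_post^2 - state$r_bar_post * r_post)
}

#' Update of the BCM sliding threshold
#'
#' One relaxation step `r_bar <- r_bar + (r_hat^2 - r_bar) / tau_bcm`,
#' where `r_hat` is the postsynaptic rate estimate of the active
#' realization (spike count based for SDP, voltage based for VDP).  The
#' round's rate estimate is squared, i.e. the threshold tracks the square
#' of the estimated rate.
#'
#' @param state A [bcm_state()].
#' @param r_post_estimate Postsynaptic rate estimate of the round (Hz, >= 0).
#' @return The updated [bcm_state()].
#' @examples
#' st <- bcm_state(r_bar_post = 4, tau_bcm = 1000)
#' bcm_threshold_update(st, 0)$r_bar_post     # 4 - 4/1000
#' @export
bcm_threshold_update <- function(state, r_post_estimate) {
  stopifnot(inherits(state, "bcm_state"), r_post_estimate >= 0)
  state$r_bar_post <- state$r_bar_post +
    (r_post_estimate^2 - state$r_bar_post) / state$tau_bcm
  state
}

#' Optimal spike-dependent (SDP) realization of a rate rule
#'
#' Minimum-variance spike-based weight update: the postsynaptic rate is
#' replaced by its spike-count ML estimate `n_post / T` and the rule is
#' evaluated at the estimate.  With `r_pre = 1` this is the per-presynaptic
#' -spike update; in the learning protocol it is scaled by the presynaptic
#' rate, to which the rule is linear.
#'
#' @param rule A [rate_rule()].
#' @param r_pre Presynaptic rate in Hz.
#' @param train Postsynaptic [spike_train()] observed during the
#'   presentation.
#' @param state A [bcm_state()] supplying the sliding threshold.
#' @return Weight change in mV.
#' @examples
#' st <- bcm_state(r_bar_post = 5, eta = 1e-6)
#' sdp_update(bcm_rule(1e-6), 10, spike_train(numeric(0), 0.5), st)  # 0
#' @export
sdp_update <- function(rule, r_pre, train, state) {
  stopifnot(inherits(rule, "rate_rule"))
  r_hat <- estimate_rate_spikes(train)
  rule$f(r_pre, r_hat, state$r_bar_post)
}

#' Optimal voltage-dependent (VDP) realization of a rate rule
#'
#' Minimum-variance voltage-based weight update: the postsynaptic rate is
#' replaced by `r(sigma_hat)` estimated from the membrane-potential trace
#' of the presentation, and the rule is evaluated at the estimate.  No
#' rate floor is applied to the estimate entering the rule.
#'
#' @inheritParams sdp_update
#' @param trace Postsynaptic [membrane_trace()] of the presentation.
#' @param params A [neuron_params()].
#' @return Weight change in mV.
#' @examples
#' st <- bcm_state(r_bar_post = 5, eta = 1e-6)
#' tr <- membrane_trace(rep(0, 11), 1e-3)
#' vdp_update(bcm_rule(1e-6), 10, tr, neuron_params(), st)   # 0
#' @export
vdp_update <- function(rule, r_pre, trace, params, state) {
  stopifnot(inherits(rule, "rate_rule"))
  r_hat <- estimate_rate_voltage(trace, params, apply_floor = FALSE)
  rule$f(r_pre, r_hat, state$r_bar_post)
}

#' Variance of the optimal SDP weight update
#'
#' Delta-method lower bound on the weight-change variance of any SDP
#' realization: `(r_post / T) * (df/dr_post)^2`.  Exact in the limit of
#' many expected spikes (`r_post * T` large); see the methods vignette for
#' the finite-window correction.
#'
#' @param rule A [rate_rule()].
#' @param r_pre,r_post Rates in Hz.
#' @param duration Presentation window T in seconds.
#' @param r_bar Sliding threshold entering the derivative (BCM).
#' @return Variance in mV^2.
#' @examples
#' sdp_update_variance(bcm_rule(1e-6), 10, 10, 0.5, r_bar = 5)
#' @export
sdp_update_variance <- function(rule, r_pre, r_post, duration, r_bar = 0) {
  stopifnot(inherits(rule, "rate_rule"), duration > 0)
  (r_post / duration) * rule$df_drpost(r_pre, r_post, r_bar)^2
}

#' Variance of the optimal VDP weight update
#'
#' Delta-method weight-change variance of the optimal voltage-based
#' realization:
#' `sigma^2 eps / (2 T) * (dr/dsigma)^2 * (df/dr_post)^2`.
#' Equals [sdp_update_variance()] divided by [time_improvement_factor()]
#' at any common window, for every rule.
#'
#' @inheritParams sdp_update_variance
#' @param params A [neuron_params()].
#' @param sigma Operating input scale in mV.
#' @param epsilon Sampling interval in seconds.
#' @return Variance in mV^2.
#' @examples
#' vdp_update_variance(bcm_rule(1e-6), 10, neuron_params(), 13.675,
#'                     1e-3, 0.01, r_bar = 5)
#' @export
vdp_update_variance <- function(rule, r_pre, params, sigma, epsilon,
                                duration, r_bar = 0) {
  stopifnot(inherits(rule, "rate_rule"), epsilon > 0, duration > 0)
  r_post <- siegert_rate(params, sigma)
  sigma^2 * epsilon / (2 * duration) *
    siegert_rate_deriv(params, sigma)^2 *
    rule$df_drpost(r_pre, r_post, r_bar)^2
}
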