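#' Neuron parameters
#'
#' Parameters of the leaky integrate-and-fire neuron in the balanced
#' (fluctuation-driven) regime.  Voltages are expressed relative to the
#' resting level, which the balanced synaptic input leaves at zero: the
#' commonly quoted absolute values (threshold -55 mV, reset -70 mV) become
#' `theta = 15`, `u_reset = 0` after subtracting the -70 mV reset/resting
#' potential.
#'
#' @param tau Membrane time constant in seconds (> 0).
#' @param theta Spike threshold in mV relative to rest (> `u_reset`).
#' @param u_reset Reset potential in mV relative to rest.
#' @param rate_floor Rate in Hz below which neuronal responses are rounded
#'   down to zero when computing selectivity (>= 0).
#'
#' @return An object of class `"neuron_params"`.
#' @examples
#' neuron_params()                      # the 15 mV effective threshold
#' neuron_params(tau = 0.01, theta = 20)
#' @export
neuron_params <- function(tau = 0.02, theta = 15, u_reset = 0, rate_floor = 1) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(u_reset), length(u_reset) == 1L, is.finite(u_reset),
            is.numeric(rate_floor), length(rate_floor) == 1L,
            is.finite(rate_floor))
  if (tau <= 0) stop("'tau' must be positive")
  if (theta <= u_reset) stop("degenerate neuron: 'theta' must exceed 'u_reset'")
  if (rate_floor < 0) stop("'rate_floor' must be non-negative")
  structure(list(tau = tau, theta = theta, u_reset = u_reset,
                 rate_floor = rate_floor),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("LIF neuron (balanced regime):\n")
  cat(sprintf("  tau = %g s, theta = %g mV, u_reset = %g mV (rel. rest), rate floor = %g Hz\n",
              x$tau, x$theta, x$u_reset, x$rate_floor))
  invisible(x)
}

#' Spike train
#'
#' An ordered set of spike times observed in a window of length `duration`.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.  May be empty.
#' @param duration Observation window length T in seconds (> 0).
#'
#' @return An object of class `"spike_train"`.
#' @examples
#' spike_train(c(0.1, 0.25, 0.4), duration = 0.5)
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (duration <= 0) stop("'duration' must be positive")
  if (length(times)) {
    if (any(!is.finite(times))) stop("spike times must be finite")
    if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
    if (times[1L] < 0 || times[length(times)] > duration)
      stop("spike times must lie in [0, duration]")
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes in %g s (%.3g Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Membrane-potential trace
#'
#' Equidistant samples of the membrane potential, `epsilon` seconds apart.
#' The reciprocal `1/epsilon` is the sampling rate.
#'
#' @param samples Numeric vector of at least two voltage samples (mV,
#'   relative to rest).
#' @param epsilon Sampling interval in seconds (> 0).
#'
#' @return An object of class `"membrane_trace"`.
#' @examples
#' membrane_trace(c(0, 1.2, -0.4), epsilon = 1e-3)
#' @export
membrane_trace <- function(samples, epsilon) {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (length(samples) < 2L) stop("a trace needs at least 2 samples")
  if (any(!is.finite(samples))) stop("voltage samples must be finite")
  structure(list(samples = samples, epsilon = epsilon), class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("Membrane trace: %d samples at %g s interval (%.4g s, sd %.3g mV)\n",
              length(x$samples), x$epsilon,
              (length(x$samples) - 1L) * x$epsilon, stats::sd(x$samples)))
  invisible(x)
}

#' Synaptic input ensemble
#'
#' Per-synapse efficacies and Poisson rates driving a Stein-model neuron.
#' With `balance_factor = 1` the weights are used as given (signed); with
#' `balance_factor = 2` the ensemble describes the mirrored
#' excitatory/inhibitory construction in which every excitatory afferent is
#' accompanied by an inhibitory one of opposite weight, doubling the input
#' variance while cancelling the mean.
#'
#' @param weights Numeric vector of synaptic efficacies w_k in mV per spike
#'   (signed).
#' @param rates Numeric vector of Poisson rates nu_k in Hz (>= 0), same
#'   length as `weights`.
#' @param balance_factor 1 (raw input) or 2 (mirrored construction).
#'
#' @return An object of class `"synaptic_input"`.
#' @examples
#' synaptic_input(weights = c(0.8, 0.8), rates = c(10, 0), balance_factor = 2)
#' @export
synaptic_input <- function(weights, rates, balance_factor = 1) {
  weights <- as.numeric(weights)
  rates <- as.numeric(rates)
  if (length(weights) != length(rates))
    stop("'weights' and 'rates' must have equal length")
  if (!length(weights)) stop("empty synaptic input")
  if (any(!is.finite(weights)) || any(!is.finite(rates)))
    stop("weights and rates must be finite")
  if (any(rates < 0)) stop("rates must be non-negative")
  if (!balance_factor %in% c(1, 2))
    stop("'balance_factor' must be 1 or 2")
  structure(list(weights = weights, rates = rates,
                 balance_factor = balance_factor),
            class = "synaptic_input")
}

#' @export
print.synaptic_input <- function(x, ...) {
  cat(sprintf("Synaptic input: %d synapses, total arrival rate %g Hz, balance factor %d\n",
              length(x$weights), sum(x$rates), x$balance_factor))
  invisible(x)
}

#' Input-variance scale of a synaptic ensemble
#'
#' The fluctuation scale sigma of the diffusion (Ornstein-Uhlenbeck)
#' approximation of the membrane potential,
#' `sigma = sqrt(balance_factor * tau * sum(w_k^2 * nu_k))` in mV.  The
#' stationary standard deviation of the membrane potential is
#' `sigma / sqrt(2)`.
#'
#' @param input A [synaptic_input()].
#' @param params A [neuron_params()].
#'
#' @return Sigma in mV (>= 0).
#' @examples
#' inp <- synaptic_input(c(0.8, 0.8), c(10, 0), balance_factor = 2)
#' input_sigma(inp, neuron_params())   # sqrt(2 * 0.02 * 0.64 * 10)
#' @export
input_sigma <- function(input, params) {
  stopifnot(inherits(input, "synaptic_input"), inherits(params, "neuron_params"))
  sqrt(input$balance_factor * params$tau * sum(input$weights^2 * input$rates))
}
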