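#' Simulate the Ornstein-Uhlenbeck membrane potential
#'
#' Draws a membrane-potential trace of the diffusion approximation
#' `du = -u/tau dt + sigma/sqrt(tau) dW` using the exact transition density
#' at the sampling step (no Euler discretization bias).
#'
#' Two modes are provided.  The default (`with_reset = FALSE`) returns the
#' free process together with an independent Poisson spike train at rate
#' `siegert_rate(params, sigma)`; this embodies the balanced-regime
#' approximation that output spiking is Poisson at the first-passage rate,
#' and action potentials do not appear in the trace.  With
#' `with_reset = TRUE` the process is integrated on a fine internal grid,
#' threshold crossings are recorded as spikes and the potential restarts at
#' `u_reset`; this mode quantifies the bias of the Poisson approximation.
#'
#' @param params A [neuron_params()].
#' @param sigma Input fluctuation scale in mV (> 0).
#' @param duration Trace duration in seconds.
#' @param epsilon Sampling interval in seconds; must not exceed `tau / 5` so
#'   that the samples resolve the membrane correlation time.
#' @param seed Optional integer seed; the call uses R's global RNG.
#' @param with_reset Logical, see Details.
#' @param sim_dt Internal integration step for the reset mode (s).  Defaults
#'   to `min(epsilon, tau / 400)`; rounded so that it divides `epsilon`.
#' @param barrier_correction Logical (reset mode).  Checking the threshold
#'   only on the discrete grid misses excursions between steps and biases
#'   the first-passage rate down; with the correction enabled the barrier
#'   is lowered by the standard continuity-correction shift
#'   `0.5826 * sigma * sqrt(sim_dt / tau)` so that the crossing statistics
#'   match the continuously monitored process to O(sim_dt).
#' @param u0 Initial potential in mV.  Defaults to a draw from the
#'   stationary law N(0, sigma^2/2) in free mode and to `u_reset` in reset
#'   mode.
#'
#' @return A list with components `trace` (a [membrane_trace()]) and
#'   `spikes` (a [spike_train()]).
#' @examples
#' sim <- simulate_oup(neuron_params(), sigma = 13.675, duration = 1,
#'                     epsilon = 1e-3, seed = 1)
#' sim$trace
#' sim$spikes
#' @export
simulate_oup <- function(params, sigma, duration, epsilon, seed = NULL,
                         with_reset = FALSE, sim_dt = NULL, u0 = NULL,
                         barrier_correction = TRUE) {
  .check_sigma(params, sigma)
  stopifnot(is.finite(duration), is.finite(epsilon), epsilon > 0)
  if (epsilon >= duration) stop("'epsilon' must be smaller than 'duration'")
  if (epsilon > params$tau / 5)
    stop("'epsilon' must not exceed tau/5: sampling must resolve the correlation time")
  if (!is.null(seed)) set.seed(seed)

  if (!with_reset) {
    n <- floor(duration / epsilon)
    a <- exp(-epsilon / params$tau)
    s <- sigma * sqrt((1 - a^2) / 2)
    if (is.null(u0)) u0 <- stats::rnorm(1, 0, sigma / sqrt(2))
    innov <- stats::rnorm(n, 0, s)
    u <- as.numeric(stats::filter(innov, a, method = "recursive",
                                  init = u0))
    trace <- membrane_trace(c(u0, u), epsilon)
    r <- siegert_rate(params, sigma)
    nsp <- stats::rpois(1, r * duration)
    spikes <- spike_train(sort(stats::runif(nsp, 0, duration)), duration)
    return(list(trace = trace, spikes = spikes))
  }

  if (is.null(sim_dt)) sim_dt <- min(epsilon, params$tau / 400)
  thin <- max(1L, as.integer(round(epsilon / sim_dt)))
  dt <- epsilon / thin
  if (is.null(u0)) u0 <- params$u_reset
  theta_sim <- params$theta -
    if (barrier_correction) 0.5826 * sigma * sqrt(dt / params$tau) else 0
  out <- oup_reset_cpp(params$tau, theta_sim, params$u_reset, sigma,
                       duration, dt, thin, u0)
  list(trace = membrane_trace(out$samples, epsilon),
       spikes = spike_train(out$spike_times, duration))
}

#' Simulate Stein's model under Poisson synaptic bombardment
#'
#' Event-driven, exact integration of the leaky integrate-and-fire neuron
#' driven by independent Poisson spike arrivals: the potential decays with
#' time constant `tau` between arrivals and jumps by `w_k` at each arrival
#' of synapse `k`; reaching the threshold emits a spike and resets the
#' potential.  With `balance_factor = 2` in the input, every synapse is
#' mirrored by an inhibitory twin (weight `-w_k`, same rate), so the mean
#' input cancels exactly while the variance doubles.
#'
#' @param input A [synaptic_input()].
#' @param params A [neuron_params()].
#' @param duration Simulated time in seconds.
#' @param epsilon Sampling interval of the returned trace (s).
#' @param seed Optional integer seed.
#' @param u0 Initial potential (mV), default 0 (the balanced resting level).
#'
#' @return A list with components `trace` and `spikes`, as in
#'   [simulate_oup()].
#' @examples
#' inp <- synaptic_input(weights = rep(0.5, 100), rates = rep(20, 100),
#'                       balance_factor = 2)
#' sim <- simulate_stein(inp, neuron_params(), duration = 1,
#'                       epsilon = 1e-3, seed = 1)
#' var(sim$trace$samples)          # ~ sigma^2 / 2
#' input_sigma(inp, neuron_params())^2 / 2
#' @export
simulate_stein <- function(input, params, duration, epsilon, seed = NULL,
                           u0 = 0) {
  stopifnot(inherits(input, "synaptic_input"), inherits(params, "neuron_params"),
            is.finite(duration), duration > 0,
            is.finite(epsilon), epsilon > 0, epsilon < duration)
  if (!is.null(seed)) set.seed(seed)
  w <- input$weights
  nu <- input$rates
  if (input$balance_factor == 2) {
    w <- c(w, -w)
    nu <- c(nu, nu)
  }
  out <- stein_cpp(w, nu, params$tau, params$theta, params$u_reset,
                   duration, epsilon, u0)
  list(trace = membrane_trace(out$samples, epsilon),
       spikes = spike_train(out$spike_times, duration))
}
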