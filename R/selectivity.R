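#' Stimulus set
#'
#' A set of `m` input-rate vectors over `N` input channels, with
#' presentation probabilities.
#'
#' @param rates An `m x N` numeric matrix of non-negative rates (Hz); row j
#'   is the j-th stimulus.
#' @param probabilities Presentation probabilities, length `m`, summing
#'   to 1.  Defaults to uniform.
#' @return An object of class `"stimulus_set"`.
#' @seealso [make_orthogonal_stimuli()], [make_gaussian_stimuli()]
#' @export
stimulus_set <- function(rates, probabilities = NULL) {
  rates <- as.matrix(rates)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("stimulus rates must be finite and non-negative")
  m <- nrow(rates)
  if (is.null(probabilities)) probabilities <- rep(1 / m, m)
  if (length(probabilities) != m || any(probabilities < 0) ||
      abs(sum(probabilities) - 1) > 1e-10)
    stop("'probabilities' must be a length-m distribution")
  structure(list(rates = rates, probabilities = probabilities),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d stimuli over %d input channels (rates %g-%g Hz)\n",
              nrow(x$rates), ncol(x$rates), min(x$rates), max(x$rates)))
  invisible(x)
}

#' Orthogonal one-hot stimuli
#'
#' Stimulus j drives input channel j at `peak_rate` and all other channels
#' at zero; stimuli are presented with uniform probability.  Requires
#' `m <= N`.
#'
#' @param N Number of input channels.
#' @param m Number of stimuli.
#' @param peak_rate Rate of the driven channel in Hz.
#' @return A [stimulus_set()].
#' @examples
#' make_orthogonal_stimuli(2, 2, 10)$rates
#' @export
make_orthogonal_stimuli <- function(N, m, peak_rate) {
  stopifnot(N >= 1, m >= 1, m <= N, peak_rate > 0)
  rates <- matrix(0, m, N)
  rates[cbind(seq_len(m), seq_len(m))] <- peak_rate
  stimulus_set(rates)
}

#' Gaussian rate-profile stimuli
#'
#' Non-orthogonal stimuli with overlapping Gaussian tuning curves: stimulus
#' j is centred at `c_j = (j - 1/2) N / m` and channel k fires at
#' `base_rate + (peak_rate - base_rate) * exp(-(k - c_j)^2 / (2 width^2))`.
#' Centres are evenly spaced without wraparound; profiles of edge stimuli
#' are truncated at the channel range.
#'
#' @inheritParams make_orthogonal_stimuli
#' @param base_rate Background rate far from the centre (Hz).
#' @param width Standard deviation of the profile in channel-index units.
#' @return A [stimulus_set()].
#' @examples
#' s <- make_gaussian_stimuli(100, 10, 10, 2, 10)
#' range(s$rates)
#' @export
make_gaussian_stimuli <- function(N, m, peak_rate, base_rate, width) {
  stopifnot(N >= 1, m >= 1, peak_rate >= base_rate, base_rate >= 0, width > 0)
  k <- seq_len(N)
  rates <- t(vapply(seq_len(m), function(j) {
    cj <- (j - 0.5) * N / m
    base_rate + (peak_rate - base_rate) * exp(-(k - cj)^2 / (2 * width^2))
  }, numeric(N)))
  stimulus_set(rates)
}

#' Network state of the feed-forward circuit
#'
#' Non-negative synaptic weights of the `N` excitatory input channels (the
#' inhibitory mirror weights are implied) together with the BCM state.
#'
#' @param weights Numeric vector of non-negative weights (mV).
#' @param bcm A [bcm_state()].
#' @return An object of class `"network_state"`.
#' @export
network_state <- function(weights, bcm = bcm_state()) {
  weights <- as.numeric(weights)
  stopifnot(all(is.finite(weights)), all(weights >= 0),
            inherits(bcm, "bcm_state"))
  structure(list(weights = weights, bcm = bcm), class = "network_state")
}

# sigma seen by the output neuron for each stimulus (rows of `rates`):
# mirrored E/I construction, each channel being a population of n_syn
# afferents that share the channel weight and rate
.stimulus_sigmas <- function(weights, stimuli, params, n_syn) {
  drop(sqrt(2 * params$tau * n_syn * (stimuli$rates %*% weights^2)))
}

#' Input selectivity of the output neuron
#'
#' `Sel(w) = 1 - E_P[r(sigma)] / max_j r(sigma_j)`, where `sigma_j` is the
#' input scale produced by stimulus j through the mirrored
#' excitatory/inhibitory feed-forward weights.  Responses below
#' `params$rate_floor` are rounded down to 0 Hz, and if every response is
#' zero the ratio is taken as 1 (0/0 = 1), giving selectivity 0.  The
#' maximum over m equiprobable stimuli is `1 - 1/m`.
#'
#' @param weights Channel weight vector (mV), or a [network_state()].
#' @param stimuli A [stimulus_set()].
#' @param params A [neuron_params()].
#' @param n_syn Afferents per input channel (the high-input-regime
#'   population size behind each channel).
#' @param rate_fun Optional fast rate map from [siegert_rate_fun()]; by
#'   default [siegert_rate()] is used directly.
#' @return Selectivity in `[0, 1)`.
#' @examples
#' stim <- make_orthogonal_stimuli(2, 2, 10)
#' selectivity(c(0.49, 0), stim, neuron_params(), n_syn = 1000)  # 0.5
#' @export
selectivity <- function(weights, stimuli, params, n_syn = 1,
                        rate_fun = NULL) {
  if (inherits(weights, "network_state")) weights <- weights$weights
  stopifnot(inherits(stimuli, "stimulus_set"), inherits(params, "neuron_params"),
            length(weights) == ncol(stimuli$rates))
  sig <- .stimulus_sigmas(weights, stimuli, params, n_syn)
  r <- numeric(length(sig))
  pos <- sig > 0
  r[pos] <- if (is.null(rate_fun)) siegert_rate(params, sig[pos]) else
    rate_fun(sig[pos])
  r[r < params$rate_floor] <- 0
  mx <- max(r)
  if (mx == 0) return(0)
  1 - sum(stimuli$probabilities * r) / mx
}

#' Run the round-based selectivity learning protocol
#'
#' Implements the stimulus-presentation protocol of the feed-forward
#' balanced circuit: in every round a stimulus is drawn from the set, the
#' output neuron is simulated for `T` seconds (Poisson spike count at
#' `r(sigma)` for the SDP realization, a free OU voltage trace sampled at
#' `epsilon` for the VDP realization), the per-channel weight update of the
#' chosen BCM realization is applied (scaled by the channel's stimulus
#' rate), the sliding threshold is relaxed towards the squared rate
#' estimate of the round, and weights are clipped at zero from below.
#'
#' `realization = "exact"` runs the noise-free rate-based iteration (the
#' rule evaluated at the true rate), which for orthogonal stimuli converges
#' to the maximally selective fixed point and serves as the reference
#' dynamics.
#'
#' @param stimuli A [stimulus_set()].
#' @param realization `"vdp"`, `"sdp"` or `"exact"`.
#' @param T Stimulus presentation duration in seconds.
#' @param rounds Number of presentations.
#' @param params A [neuron_params()].
#' @param init_weights Initial channel weights in mV (scalar recycled).
#' @param eta BCM step size.
#' @param tau_bcm Sliding-threshold time constant in rounds.
#' @param rbar_init Initial sliding threshold.
#' @param epsilon Voltage sampling interval in seconds (VDP).
#' @param n_syn Afferents per input channel.
#' @param clip_weights Clip weights at 0 from below (excitatory synapses).
#' @param presyn_mode `"true_rate"` (presynaptic factor is the stimulus
#'   rate) or `"spike_estimate"` (Poisson spike-count estimate of it).
#' @param seed Optional integer seed.
#' @param log_every Record the state every this many rounds (round 1 and
#'   the last round are always recorded).
#'
#' @return A data frame with one row per logged round: `round`, `stimulus`,
#'   `rbar`, `selectivity` and weight columns `w_1 ... w_N`; the final
#'   weights and BCM state are attached as attributes `final_weights` and
#'   `final_state`.
#' @examples
#' stim <- make_orthogonal_stimuli(2, 2, 10)
#' run <- run_protocol(stim, "exact", T = 0.01, rounds = 3000,
#'                     params = neuron_params(), init_weights = 0.8,
#'                     seed = 1, log_every = 100)
#' tail(run$selectivity, 1)
#' @export
run_protocol <- function(stimuli, realization = c("vdp", "sdp", "exact"),
                         T, rounds, params, init_weights,
                         eta = 1e-6, tau_bcm = 1000, rbar_init = 5,
                         epsilon = 1e-3, n_syn = 1000, clip_weights = TRUE,
                         presyn_mode = c("true_rate", "spike_estimate"),
                         seed = NULL, log_every = 1) {
  realization <- match.arg(realization)
  presyn_mode <- match.arg(presyn_mode)
  stopifnot(inherits(stimuli, "stimulus_set"), inherits(params, "neuron_params"),
            T > 0, rounds >= 1)
  if (!is.null(seed)) set.seed(seed)

  N <- ncol(stimuli$rates)
  m <- nrow(stimuli$rates)
  w <- rep_len(pmax(init_weights, 0), N)
  rbar <- rbar_init
  rate_fun <- siegert_rate_fun(params)

  a <- exp(-epsilon / params$tau)
  n_samp <- max(1L, floor(T / epsilon))
  if (realization == "vdp" && T < epsilon)
    stop("'T' must be at least one sampling interval for the VDP realization")

  log_rounds <- unique(c(1L, seq(1L, rounds, by = log_every), rounds))
  log_rounds <- sort(log_rounds)
  nl <- length(log_rounds)
  out_round <- integer(nl); out_stim <- integer(nl)
  out_rbar <- numeric(nl); out_sel <- numeric(nl)
  out_w <- matrix(0, nl, N)
  li <- 1L

  js <- sample.int(m, rounds, replace = TRUE, prob = stimuli$probabilities)
  for (i in seq_len(rounds)) {
    j <- js[i]
    nu <- stimuli$rates[j, ]
    sig <- sqrt(2 * params$tau * n_syn * sum(w^2 * nu))
    r_true <- rate_fun(sig)

    r_hat <- switch(realization,
      exact = r_true,
      sdp = stats::rpois(1, r_true * T) / T,
      vdp = {
        s <- sig * sqrt((1 - a^2) / 2)
        u0 <- stats::rnorm(1, 0, sig / sqrt(2))
        u <- c(u0, as.numeric(stats::filter(stats::rnorm(n_samp, 0, s), a,
                                            method = "recursive", init = u0)))
        sig_hat <- {
          dd <- u[-1L] - a * u[-length(u)]
          sqrt(2 * sum(dd^2) / (n_samp * (1 - a^2)))
        }
        rate_fun(sig_hat)
      })

    pre <- if (presyn_mode == "true_rate") nu else
      stats::rpois(N, nu * T) / T
    w <- w + pre * eta * (r_hat^2 - rbar * r_hat)
    if (clip_weights) w <- pmax(w, 0)
    rbar <- rbar + (r_hat^2 - rbar) / tau_bcm

    if (li <= nl && i == log_rounds[li]) {
      out_round[li] <- i
      out_stim[li] <- j
      out_rbar[li] <- rbar
      out_sel[li] <- selectivity(w, stimuli, params, n_syn, rate_fun)
      out_w[li, ] <- w
      li <- li + 1L
    }
  }

  res <- data.frame(round = out_round, stimulus = out_stim, rbar = out_rbar,
                    selectivity = out_sel)
  wdf <- as.data.frame(out_w)
  names(wdf) <- paste0("w_", seq_len(N))
  res <- cbind(res, wdf)
  attr(res, "final_weights") <- w
  attr(res, "final_state") <- bcm_state(r_bar_post = max(rbar, 0), eta = eta,
                                        tau_bcm = tau_bcm)
  attr(res, "realization") <- realization
  res
}
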