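# Experiment drivers: reproducible tables behind the estimator-variance and
# selectivity figures, plus deterministic test fixtures.  All drivers take an
# explicit seed and return plain data frames so that plotting stays separate
# from data generation.

#' Estimator standard deviation versus stimulus duration
#'
#' For each duration on a (log-spaced) grid, computes the analytic standard
#' deviations of the spike-count and voltage-based rate estimators
#' (`sqrt(r/T)` and the delta-method form) and their empirical counterparts
#' over `trials` simulated presentations at a fixed operating rate.
#'
#' @param params A [neuron_params()].
#' @param rate Operating firing rate in Hz.
#' @param epsilon Voltage sampling interval in seconds.
#' @param durations Stimulus durations in seconds.
#' @param trials Simulated presentations per duration.
#' @param seed Optional integer seed.
#' @return A data frame with columns `duration`, `sd_spike_analytic`,
#'   `sd_spike_empirical`, `sd_voltage_analytic`, `sd_voltage_empirical`.
#' @examples
#' fig1_variance_table(neuron_params(), durations = c(0.05, 0.2),
#'                     trials = 50, seed = 1)
#' @export
fig1_variance_table <- function(params, rate = 10, epsilon = 1e-3,
                                durations = 10^seq(-3, 0, length.out = 13),
                                trials = 100, seed = NULL) {
  stopifnot(inherits(params, "neuron_params"), rate > 0, trials >= 2)
  if (!is.null(seed)) set.seed(seed)
  sigma <- sigma_for_rate(params, rate)
  a <- exp(-epsilon / params$tau)
  s <- sigma * sqrt((1 - a^2) / 2)
  rate_fun <- siegert_rate_fun(params)
  rows <- lapply(durations, function(T) {
    n_hat <- stats::rpois(trials, rate * T)
    sd_sp <- stats::sd(n_hat / T)
    n_samp <- max(1L, floor(T / epsilon))
    r_hat <- vapply(seq_len(trials), function(i) {
      z <- stats::rnorm(n_samp, 0, s)
      sig_hat <- sqrt(2 * sum(z^2) / (n_samp * (1 - a^2)))
      rate_fun(sig_hat)
    }, numeric(1))
    data.frame(duration = T,
               sd_spike_analytic = sqrt(spike_estimator_variance(rate, T)),
               sd_spike_empirical = sd_sp,
               sd_voltage_analytic =
                 sqrt(voltage_estimator_variance(params, sigma, epsilon,
                                                 n_samp * epsilon)),
               sd_voltage_empirical = stats::sd(r_hat))
  })
  do.call(rbind, rows)
}

#' Time-improvement factor versus sampling rate
#'
#' Tabulates [time_improvement_factor()] over a sampling-rate grid for a
#' set of operating firing rates.
#'
#' @param params A [neuron_params()].
#' @param rates Operating firing rates in Hz.
#' @param sampling_rates Sampling rates 1/epsilon in Hz.
#' @return A data frame with columns `rate`, `sampling_rate`, `factor`.
#' @examples
#' fig1_improvement_table(neuron_params(), rates = c(10, 20, 40),
#'                        sampling_rates = 1000)
#' @export
fig1_improvement_table <- function(params, rates = c(10, 20, 40),
                                   sampling_rates = 10^seq(2, 4, length.out = 9)) {
  grid <- expand.grid(rate = rates, sampling_rate = sampling_rates)
  grid$factor <- mapply(function(r, fs)
    time_improvement_factor(params, r, 1 / fs),
    grid$rate, grid$sampling_rate)
  grid
}

#' Weight-change uncertainty bands versus stimulus duration
#'
#' Analytic one-standard-deviation bands of the BCM weight change applied
#' by the optimal SDP and VDP realizations as a function of the
#' presentation duration, around the desired (noise-free) change.
#'
#' @param params A [neuron_params()].
#' @param rate Postsynaptic operating rate in Hz.
#' @param r_pre Presynaptic rate in Hz.
#' @param r_bar Sliding threshold.
#' @param eta BCM step size.
#' @param epsilon Sampling interval in seconds.
#' @param durations Durations in seconds.
#' @return A data frame with `duration`, `delta_w`, `sd_sdp`, `sd_vdp`.
#' @export
fig1_weight_change_table <- function(params, rate = 10, r_pre = 10,
                                     r_bar = 5, eta = 1e-6, epsilon = 1e-3,
                                     durations = 10^seq(-3, 0, length.out = 13)) {
  sigma <- sigma_for_rate(params, rate)
  rule <- bcm_rule(eta)
  st <- bcm_state(r_bar_post = r_bar, eta = eta)
  data.frame(
    duration = durations,
    delta_w = bcm_delta_w(r_pre, rate, st),
    sd_sdp = sqrt(vapply(durations, function(T)
      sdp_update_variance(rule, r_pre, rate, T, r_bar), numeric(1))),
    sd_vdp = sqrt(vapply(durations, function(T)
      vdp_update_variance(rule, r_pre, params, sigma, epsilon, T, r_bar),
      numeric(1))))
}

#' Run a preconfigured selectivity learning experiment
#'
#' Wraps [run_protocol()] with the two standard task configurations: the
#' orthogonal two-stimulus task (N = 2, m = 2, peak 10 Hz, initial weights
#' 0.8 mV) and the overlapping Gaussian-profile task (N = 100, m = 10,
#' peak 10 Hz, base 2 Hz, width 10, initial weights 0.1 mV).  All
#' parameters can be overridden through `...`, which is passed on to
#' [run_protocol()].
#'
#' @param task `"orthogonal"` or `"gaussian"`.
#' @param realization `"vdp"`, `"sdp"` or `"exact"`.
#' @param T Stimulus presentation duration in seconds.
#' @param rounds Number of presentations.
#' @param params A [neuron_params()].
#' @param seed Optional integer seed.
#' @param ... Further arguments to [run_protocol()].
#' @return See [run_protocol()].
#' @examples
#' run <- run_selectivity_experiment("orthogonal", "exact", rounds = 2000,
#'                                   seed = 1, log_every = 200)
#' tail(run$selectivity, 1)
#' @export
run_selectivity_experiment <- function(task = c("orthogonal", "gaussian"),
                                       realization = c("vdp", "sdp", "exact"),
                                       T = 0.01, rounds = 20000,
                                       params = neuron_params(), seed = NULL,
                                       ...) {
  task <- match.arg(task)
  realization <- match.arg(realization)
  if (task == "orthogonal") {
    stimuli <- make_orthogonal_stimuli(2, 2, 10)
    init_w <- 0.8
  } else {
    stimuli <- make_gaussian_stimuli(100, 10, 10, 2, 10)
    init_w <- 0.1
  }
  run_protocol(stimuli, realization, T = T, rounds = rounds, params = params,
               init_weights = init_w, seed = seed, ...)
}

#' Write deterministic CSV fixtures
#'
#' Generates the small fixture files used by the test suite: a 1 s free OU
#' trace at the 10 Hz operating point, a 10 Hz Poisson spike train and the
#' two-stimulus orthogonal set, all seeded so that identical seeds give
#' byte-identical files.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param params A [neuron_params()].
#' @return Invisibly, the named vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 1, params = neuron_params()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sigma <- sigma_for_rate(params, 10)
  sim <- simulate_oup(params, sigma, duration = 1, epsilon = 1e-3,
                      seed = seed)
  paths <- c(trace = file.path(dir, "oup_trace_1s.csv"),
             spikes = file.path(dir, "poisson_10hz.csv"),
             stimuli = file.path(dir, "orthogonal_2x2.csv"))
  write_trace(sim$trace, paths["trace"],
              meta = list(sigma_mV = sigma, tau_s = params$tau, seed = seed))
  write_spike_train(sim$spikes, paths["spikes"],
                    meta = list(rate_hz = 10, seed = seed))
  write_stimulus_set(make_orthogonal_stimuli(2, 2, 10), paths["stimuli"])
  invisible(paths)
}
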