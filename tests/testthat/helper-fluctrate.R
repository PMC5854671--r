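# Shared fixtures for the test suite.
#
# Frozen oracle values for the first-passage rate map, computed once with an
# independent fine-grid trapezoidal quadrature (2e6 nodes) of the scaled-erfc
# integrand, NOT with the package's adaptive quadrature:
#   r(sigma = 10)  = 3.867525 Hz
#   r(sigma = 16)  = 14.20771 Hz
#   sigma(r = 10)  = 13.67516 mV   (root of the trapezoid map)
RATE_AT_SIGMA10 <- 3.867525
RATE_AT_SIGMA16 <- 14.20771
SIGMA_AT_10HZ <- 13.67516

default_params <- function() neuron_params()

# free OU sigma-hat replicates at the exact transition, one column per trace;
# returns the per-trace estimates computed through the package estimator
replicate_sigma_hat <- function(params, sigma, n_samples, n_traces, epsilon = 1e-3) {
  a <- exp(-epsilon / params$tau)
  s <- sigma * sqrt((1 - a^2) / 2)
  vapply(seq_len(n_traces), function(i) {
    u0 <- stats::rnorm(1, 0, sigma / sqrt(2))
    u <- c(u0, as.numeric(stats::filter(stats::rnorm(n_samples, 0, s), a,
                                        method = "recursive", init = u0)))
    estimate_sigma_voltage(membrane_trace(u, epsilon), params)
  }, numeric(1))
}
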