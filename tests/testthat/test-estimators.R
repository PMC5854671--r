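test_that("spike-count estimator and its variance follow the Poisson law", {
  expect_equal(estimate_rate_spikes(spike_train(seq(0.05, 0.45, 0.1), 0.5)), 10)
  expect_equal(estimate_rate_spikes(spike_train(numeric(0), 2)), 0)
  expect_equal(spike_estimator_variance(10, 0.5), 20)
  expect_equal(spike_estimator_variance(10, 1), spike_estimator_variance(10, 2) * 2)
  set.seed(51)
  r_hat <- rpois(1e4, 10 * 0.5) / 0.5
  # Var(n/T) = r/T; SE of the sample variance from the 4th Poisson moment:
  # Var((n - lam)^2) = 2 lam^2 + lam
  se <- sqrt((2 * 5^2 + 5) / 1e4) / 0.5^2
  expect_lt(abs(var(r_hat) - 20), 3 * se)
  expect_lt(abs(mean(r_hat) - 10), 2 * sd(r_hat) / sqrt(1e4))
})

test_that("sigma-hat has its closed algebraic form on degenerate traces", {
  p <- default_params()
  expect_equal(estimate_sigma_voltage(membrane_trace(rep(0, 50), 1e-3), p), 0)
  a <- exp(-1e-3 / p$tau)
  for (c0 in c(3, -7)) {
    tr <- membrane_trace(rep(c0, 20), 1e-3)
    expect_equal(estimate_sigma_voltage(tr, p),
                 abs(c0) * sqrt(2 * (1 - a) / (1 + a)), tolerance = 1e-12)
  }
})

test_that("sigma-hat recovers the generating sigma with the stated precision", {
  p <- default_params()
  set.seed(52)
  sh <- replicate_sigma_hat(p, 14, n_samples = 1e4, n_traces = 500)
  expect_lt(abs(mean(sh) - 14) / 14, 0.01)
  v_true <- 14^2 * 1e-3 / (2 * 10)          # sigma^2 eps / (2 T)
  se <- v_true * sqrt(2 / 499)
  expect_lt(abs(var(sh) - v_true), 3 * se)
})

test_that("voltage rate estimate composes the rate map with sigma-hat", {
  p <- default_params()
  a <- exp(-1e-3 / p$tau)
  # constant trace engineered so that sigma-hat equals the 10 Hz operating point
  c0 <- SIGMA_AT_10HZ / sqrt(2 * (1 - a) / (1 + a))
  tr <- membrane_trace(rep(c0, 30), 1e-3)
  expect_equal(estimate_rate_voltage(tr, p), 10, tolerance = 1e-4)
  expect_equal(estimate_rate_voltage(membrane_trace(rep(0, 30), 1e-3), p), 0)
  # the floor rounds a ~0.5 Hz estimate to zero unless disabled
  c1 <- 7 / sqrt(2 * (1 - a) / (1 + a))    # r(7 mV) ~ 0.53 Hz < 1 Hz floor
  tr1 <- membrane_trace(rep(c1, 30), 1e-3)
  expect_equal(estimate_rate_voltage(tr1, p), 0)
  expect_gt(estimate_rate_voltage(tr1, p, apply_floor = FALSE), 0.1)
})

test_that("voltage estimator variance matches simulation at the operating point", {
  p <- default_params()
  sigma <- SIGMA_AT_10HZ
  rfun <- siegert_rate_fun(p)
  # exact sampling law at n samples: n sigma_hat^2 / sigma^2 ~ chi-squared(n),
  # so the exact moments of r(sigma_hat) follow by quadrature -- an oracle
  # independent of the delta method
  chisq_moments <- function(n) {
    mom <- function(pow) stats::integrate(function(x)
      stats::dchisq(x, n) * rfun(sigma * sqrt(x / n))^pow, 0, Inf,
      rel.tol = 1e-9)$value
    m1 <- mom(1); m2 <- mom(2); m4c <- stats::integrate(function(x)
      stats::dchisq(x, n) * (rfun(sigma * sqrt(x / n)) - m1)^4, 0, Inf,
      rel.tol = 1e-9)$value
    list(mean = m1, var = m2 - m1^2, m4 = m4c)
  }
  ex10 <- chisq_moments(10)
  v8 <- voltage_estimator_variance(p, sigma, 1e-3, 0.01)
  # the 10 ms window (10 samples): the exact variance sits 10.4% below the
  # delta-method value (frozen oracle ratio 0.8961)
  expect_equal(ex10$var / v8, 0.8961, tolerance = 1e-3)
  set.seed(53)
  sh <- replicate_sigma_hat(p, sigma, n_samples = 10, n_traces = 1e4)
  r_hat <- rfun(sh)
  expect_lt(abs(var(r_hat) - ex10$var),
            3 * sqrt((ex10$m4 - ex10$var^2) / 1e4))
  expect_lt(abs(mean(r_hat) - ex10$mean), 3 * sd(r_hat) / sqrt(1e4))
  # unbiasedness is an asymptotic property: at 200 samples the estimator
  # mean sits within 3 SE of the true rate
  sh2 <- replicate_sigma_hat(p, sigma, n_samples = 200, n_traces = 1e4)
  r_hat2 <- rfun(sh2)
  expect_lt(abs(mean(r_hat2) - 10), 3 * sd(r_hat2) / sqrt(1e4))
})

test_that("estimator variances scale as stated in eps and T", {
  p <- default_params()
  v <- voltage_estimator_variance(p, 12, 1e-3, 0.1)
  expect_equal(voltage_estimator_variance(p, 12, 2e-3, 0.1), 2 * v)
  expect_equal(voltage_estimator_variance(p, 12, 1e-3, 0.2), v / 2)
})

test_that("unbalanced variance generalizes the balanced formula", {
  p <- default_params()
  v_bal <- voltage_estimator_variance(p, 12, 1e-3, 0.1)
  d <- siegert_rate_deriv(p, 12)
  expect_equal(voltage_estimator_variance_unbalanced(p, 12, 0, 1e-3, 0.1,
                                                     dr_dsigma = d, dr_dmu = 0),
               v_bal, tolerance = 1e-12)
  # mean-term is independent of the sampling interval
  v1 <- voltage_estimator_variance_unbalanced(p, 12, 1, 1e-3, 0.1, 0, 2)
  v2 <- voltage_estimator_variance_unbalanced(p, 12, 1, 1e-4, 0.1, 0, 2)
  expect_equal(v1, v2)
  # with equal partials the term ratio is eps / (2 tau)
  eps <- 1e-3
  va <- voltage_estimator_variance_unbalanced(p, 12, 1, eps, 0.1, 1, 0)
  vb <- voltage_estimator_variance_unbalanced(p, 12, 1, eps, 0.1, 0, 1)
  expect_equal(va / vb, eps / (2 * p$tau), tolerance = 1e-12)
})

test_that("time-improvement factor equals the variance ratio and scales in eps", {
  p <- default_params()
  f <- time_improvement_factor(p, 10, 1e-3)
  expect_gt(f, 10)
  expect_equal(time_improvement_factor(p, 10, 5e-4), 2 * f, tolerance = 1e-9)
  sigma <- sigma_for_rate(p, 10)
  for (T in c(0.01, 0.37)) {
    ratio <- spike_estimator_variance(10, T) /
      voltage_estimator_variance(p, sigma, 1e-3, T)
    expect_equal(f, ratio, tolerance = 1e-9)
  }
})

test_that("coverage probabilities and minimal windows are consistent", {
  # exact Poisson: 10 Hz +- 5 Hz in 0.5 s means 3..7 spikes out of Pois(5)
  expect_equal(spike_coverage(10, 0.5, 5), ppois(7, 5) - ppois(2, 5),
               tolerance = 1e-12)
  expect_gt(spike_coverage(10, 0.5, 5), 0.70)
  g <- spike_coverage(10, 0.5, 5, method = "gaussian")
  expect_equal(g, pnorm(5 / sqrt(20)) - pnorm(-5 / sqrt(20)))
  p <- default_params()
  Tmin <- min_duration_voltage(p, 10, 1e-3)
  expect_equal(voltage_coverage(p, 10, 1e-3, Tmin, 5), 0.70, tolerance = 1e-9)
  expect_lt(voltage_coverage(p, 10, 1e-3, Tmin / 2, 5), 0.70)
  ms <- min_duration_spikes(10)
  expect_equal(ms$gaussian, 10 * qnorm(0.85)^2 / 25, tolerance = 1e-12)
  expect_gte(spike_coverage(10, ms$exact, 5), 0.70)
})
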