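test_that("BCM weight change and sliding threshold follow their recursions", {
  st <- bcm_state(r_bar_post = 5, eta = 1e-6)
  expect_equal(bcm_delta_w(10, 10, st), 5e-4)
  expect_equal(bcm_delta_w(10, 5, st), 0)       # LTD/LTP crossover
  expect_equal(bcm_delta_w(0, 42, st), 0)       # presynaptic gating
  expect_lt(bcm_delta_w(10, 3, st), 0)          # LTD below threshold
  # fixed point and geometric relaxation of the threshold
  st2 <- bcm_state(r_bar_post = 100, tau_bcm = 50)
  expect_equal(bcm_threshold_update(st2, 10)$r_bar_post, 100)
  st3 <- bcm_state(r_bar_post = 4, tau_bcm = 1000)
  expect_equal(bcm_threshold_update(st3, 0)$r_bar_post, 4 - 4 / 1000)
  rbar <- 2; r <- 7
  for (k in 1:25) rbar <- bcm_threshold_update(
    bcm_state(rbar, tau_bcm = 30), r)$r_bar_post
  expect_equal(rbar, r^2 + (2 - r^2) * (1 - 1 / 30)^25, tolerance = 1e-12)
})

test_that("SDP and VDP updates vanish where the rule vanishes", {
  p <- default_params()
  rule <- bcm_rule(1e-6)
  st <- bcm_state(r_bar_post = 5, eta = 1e-6)
  expect_equal(sdp_update(rule, 10, spike_train(numeric(0), 0.5), st), 0)
  # spike count landing exactly on the threshold rate
  tr5 <- spike_train(seq(0.1, 0.9, length.out = 5) , 1)  # 5 Hz = r_bar
  expect_equal(sdp_update(rule, 10, tr5, st), 0)
  expect_equal(vdp_update(rule, 10, membrane_trace(rep(0, 11), 1e-3), p, st), 0)
  # constant trace engineered so that r(sigma-hat) = r_bar
  a <- exp(-1e-3 / p$tau)
  c0 <- sigma_for_rate(p, 5) / sqrt(2 * (1 - a) / (1 + a))
  expect_equal(vdp_update(rule, 10, membrane_trace(rep(c0, 11), 1e-3), p, st),
               0, tolerance = 1e-12)
})

test_that("SDP update variance matches the exact Poisson-moment oracle", {
  # exact moments by enumeration over the Poisson mass (independent oracle)
  eta <- 1e-6; r_pre <- 10; r_post <- 10; rbar <- 5; T <- 0.5
  lam <- r_post * T
  k <- 0:300
  pk <- dpois(k, lam)
  y <- eta * r_pre * ((k / T)^2 - rbar * (k / T))
  mu_y <- sum(pk * y)
  v_exact <- sum(pk * y^2) - mu_y^2
  m4 <- sum(pk * (y - mu_y)^4)
  set.seed(61)
  st <- bcm_state(r_bar_post = rbar, eta = eta)
  rule <- bcm_rule(eta)
  upd <- vapply(rpois(1e4, lam), function(n) {
    tt <- if (n > 0) seq(0, T * 0.999, length.out = n) else numeric(0)
    sdp_update(rule, r_pre, spike_train(tt, T), st)
  }, numeric(1))
  se_var <- sqrt((m4 - v_exact^2) / 1e4)
  expect_lt(abs(var(upd) - v_exact), 3 * se_var)
  expect_lt(abs(mean(upd) - mu_y), 3 * sd(upd) / sqrt(1e4))
  # the delta-method formula is a large-window limit of the exact variance
  expect_gt(v_exact / sdp_update_variance(rule, r_pre, r_post, T, rbar), 1.2)
  for (Tlong in c(5, 50)) {
    lamL <- r_post * Tlong
    kL <- 0:(lamL + 12 * sqrt(lamL))
    pkL <- dpois(kL, lamL)
    yL <- eta * r_pre * ((kL / Tlong)^2 - rbar * (kL / Tlong))
    vL <- sum(pkL * yL^2) - sum(pkL * yL)^2
    rel <- sdp_update_variance(rule, r_pre, r_post, Tlong, rbar) / vL - 1
    expect_lt(abs(rel), if (Tlong == 5) 0.05 else 0.006)
  }
})

test_that("VDP update variance matches simulation in its asymptotic regime", {
  p <- default_params()
  eta <- 1e-6; r_pre <- 10; rbar <- 5
  sigma <- SIGMA_AT_10HZ
  rule <- bcm_rule(eta)
  st <- bcm_state(r_bar_post = rbar, eta = eta)
  set.seed(62)
  T <- 0.1
  sh <- replicate_sigma_hat(p, sigma, n_samples = 100, n_traces = 5000)
  r_hat <- siegert_rate_fun(p)(sh)
  upd <- eta * r_pre * (r_hat^2 - rbar * r_hat)
  v13 <- vdp_update_variance(rule, r_pre, p, sigma, 1e-3, T, rbar)
  expect_lt(abs(var(upd) - v13) / v13, 0.15)
  # at n = 100 samples the residual delta-method bias is ~6% of Delta_w
  dw <- bcm_delta_w(r_pre, 10, st)
  expect_lt(abs(mean(upd) - dw) / dw, 0.10)
})

test_that("variance formulas scale in T and eps and obey the improvement identity", {
  p <- default_params()
  rule <- bcm_rule(1e-6)
  sigma <- sigma_for_rate(p, 10)
  v_s <- sdp_update_variance(rule, 10, 10, 0.1, r_bar = 5)
  expect_equal(sdp_update_variance(rule, 10, 10, 0.2, r_bar = 5), v_s / 2)
  expect_equal(sdp_update_variance(linear_rule(0), 10, 10, 0.1), 0)
  v_v <- vdp_update_variance(rule, 10, p, sigma, 1e-3, 0.1, r_bar = 5)
  expect_equal(vdp_update_variance(rule, 10, p, sigma, 2e-3, 0.1, r_bar = 5),
               2 * v_v)
  expect_equal(v_s / v_v, time_improvement_factor(p, 10, 1e-3),
               tolerance = 1e-9)
})

test_that("the SDP/VDP variance ratio does not depend on the rule", {
  p <- default_params()
  sigma <- sigma_for_rate(p, 10)
  ratio <- function(rule, rbar = 0) {
    sdp_update_variance(rule, 10, 10, 0.05, rbar) /
      vdp_update_variance(rule, 10, p, sigma, 1e-3, 0.05, rbar)
  }
  r_bcm <- ratio(bcm_rule(1e-6), rbar = 5)
  r_lin <- ratio(linear_rule(3))
  expect_equal(r_bcm, r_lin, tolerance = 1e-9)
  expect_equal(r_bcm, time_improvement_factor(p, 10, 1e-3), tolerance = 1e-9)
})
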