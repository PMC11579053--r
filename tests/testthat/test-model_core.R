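test_that("steady-state gain equals the converged Riccati fixed point", {
  for (rho in c(1e-3, 0.1, 2, 50, 1e4)) {
    expect_equal(steady_state_gain(rho), riccati_gain_oracle(rho),
                 tolerance = 1e-12)
  }
  # frozen closed-form case: rho = 2 => M = 2, K = 0.5
  expect_equal(steady_state_gain(2), 0.5)
  # limits: perfect sensor and useless sensor
  expect_gt(steady_state_gain(1e-8), 1 - 1e-3)
  expect_lt(steady_state_gain(1e6), 1e-2)
  # strictly decreasing in rho
  grid <- 10^seq(-3, 4, length.out = 40)
  expect_true(all(diff(steady_state_gain(grid)) < 0))
  expect_error(steady_state_gain(0), "rho")
  expect_error(steady_state_gain(-1), "rho")
})

test_that("Kalman filter handles degenerate inputs as expected", {
  y <- rep(5.5, 20)
  kf <- kalman_filter(y, rho = 3)
  expect_equal(kf$c_hat, y)                   # zero innovation throughout
  expect_true(all(kf$kgain > 0 & kf$kgain <= 1))

  y2 <- c(5, 5.4, 6, 6.6, 7)
  kf2 <- kalman_filter(y2, rho = 1e-10)
  expect_equal(kf2$c_hat, y2, tolerance = 1e-6)  # near-perfect sensor tracks

  expect_error(kalman_filter(c(5, NA, 6), 1), "non-finite")
  expect_error(kalman_filter(numeric(0), 1), "nonempty")
  expect_error(kalman_filter(y2, rho = 0), "rho")
})

test_that("Kalman posterior means match a brute-force grid Bayesian filter", {
  y <- seq(5.2, 7.5, length.out = 36)          # rebreathing-like ramp
  for (rho in c(0.1, 1, 5, 10)) {
    kf <- kalman_filter(y, rho)
    oracle <- grid_filter_oracle(y, rho)
    expect_lt(max(abs(kf$c_hat - oracle)), 1e-3)
  }
})

test_that("per-bin Kalman gain settles to the steady-state value", {
  y <- rep(6, 300)
  for (rho in c(1e-3, 0.5, 20)) {
    kf <- kalman_filter(y, rho)
    expect_lt(abs(kf$kgain[300] - steady_state_gain(rho)), 1e-10)
  }
})

test_that("activity effect follows its closed form and saturates", {
  a <- activity_trajectory(A = 1, tau_a = 40, n_bins = 36, bin_s = 10)
  expect_equal(a, activity_recursion_oracle(1, 40, 36, 10),
               tolerance = 1e-12)
  expect_equal(a, 1 - 0.75^(1:36))
  expect_equal(a[12], 1 - 0.75^12)     # ~0.968 at the 2 min mark
  expect_gte(a[12], 0.95)
  expect_true(all(diff(a) > 0))

  expect_equal(activity_trajectory(0, 40, 36), rep(0, 36))
  expect_equal(activity_trajectory(-1, 40, 36),
               -activity_trajectory(1, 40, 36))
  expect_warning(activity_trajectory(1, tau_a = 5, n_bins = 5, bin_s = 10),
                 "overshoot")
  expect_error(activity_trajectory(1, tau_a = 0, n_bins = 5), "tau_a")
})

test_that("respiratory state matches the recursion oracle and its limits", {
  pars <- model_params(rho = 1, w_c = 0.5, A = 10, gain = 1, offset = 0)
  n <- 36
  c_hat <- seq(5.2, 7.4, length.out = n)
  a <- activity_trajectory(10, 40, n)

  x <- respiratory_state(c_hat, a, pars, "full")
  expect_equal(x, state_recursion_oracle(c_hat, a, 0.8, 0.5, 5),
               tolerance = 1e-12)

  # w_c = 0, A = 0: no input, state stays at rest
  p0 <- model_params(rho = 1, w_c = 0, A = 0, gain = 1, offset = 0)
  expect_equal(respiratory_state(c_hat, a, p0, "full"), rep(0, n))

  # memoryless variant with no activity is pointwise in the CO2 estimate
  pm <- model_params(rho = 1, w_c = 0.7, A = 0, gain = 1, offset = 0)
  expect_equal(respiratory_state(c_hat, a, pm, "no_memory"),
               0.7 * (c_hat - 5), tolerance = 1e-12)

  # no_memory equals the full recursion with alpha = 0 on identical inputs
  pa <- model_params(rho = 1, w_c = 0.6, A = 4, gain = 1, offset = 0,
                     alpha = 0)
  expect_equal(respiratory_state(c_hat, a, pa, "full"),
               respiratory_state(c_hat, a,
                                 model_params(rho = 1, w_c = 0.6, A = 4,
                                              gain = 1, offset = 0),
                                 "no_memory"))

  expect_error(respiratory_state(c_hat, a[-1], pars), "length")
})

test_that("constant sensory input drives the state to its geometric limit", {
  # limit of x_t = (1-w)(alpha x) + w d  is  w d / (1 - alpha (1 - w))
  for (w in c(0.3, 0.7, 1)) {
    pars <- model_params(rho = 1, w_c = w, A = 0, gain = 1, offset = 0)
    c_hat <- rep(6, 30)                # 1 % CO2 above the setpoint
    x <- respiratory_state(c_hat, rep(0, 30), pars, "full")
    lim <- w * 1 / (1 - 0.8 * (1 - w))
    expect_equal(x[30], lim, tolerance = 1e-3)
    oracle <- state_recursion_oracle(c_hat, rep(0, 30), 0.8, w, 5)
    expect_equal(x, oracle, tolerance = 1e-12)
  }
})

test_that("readout is linear and clipped to the rating scale", {
  expect_equal(readout(50, 1, 0), 50)
  expect_equal(readout(200, 1, 0), 100)
  expect_equal(readout(-10, 1, 0), 0)
  expect_equal(readout(c(1, 2, 3), 0, 40), rep(40, 3))
  expect_equal(readout(c(1, 2), 2, 150), c(100, 100))
})

test_that("forward model composes the cascade and is deterministic", {
  prof <- profile_persistent(seed = 9)
  et <- generate_co2_trace(prof)
  pars <- prof$true_params

  t1 <- forward_model(et, pars, "full")
  t2 <- forward_model(et, pars, "full")
  expect_identical(t1, t2)
  expect_true(all(t1$b_pred >= 0 & t1$b_pred <= 100))
  expect_true(all(t1$kgain > 0 & t1$kgain <= 1))
  expect_equal(nrow(t1), 36)

  # with no sensory weight and no activity the prediction is the offset
  p0 <- model_params(rho = 1, w_c = 0, A = 0, gain = 3, offset = 12)
  expect_equal(forward_model(et, p0)$b_pred, rep(12, 36))

  # full and no_activity coincide when A = 0
  pa <- model_params(rho = 0.5, w_c = 0.6, A = 0, gain = 10, offset = 5)
  expect_identical(forward_model(et, pa, "full")$b_pred,
                   forward_model(et, pa, "no_activity")$b_pred)
  expect_error(forward_model(et, pa, "linear_regression"), "latent")
})

test_that("prediction-dominated parameters decouple ratings from CO2", {
  prof <- profile_persistent(seed = 21, rating_noise_sd = 0)
  et <- generate_co2_trace(prof)
  traj <- forward_model(et, prof$true_params, "full")
  last60 <- 31:36
  expect_gte(mean(traj$b_pred[last60]), 0.5 * max(traj$b_pred))
  expect_lte(abs(mean(et[last60]) - prof$baseline_pct), 0.3)
})
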