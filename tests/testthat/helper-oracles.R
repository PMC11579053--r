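# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Fixed point of the scalar random-walk Riccati recursion, by brute
# iteration: P <- (1 - K) (P + 1), K = (P + 1) / (P + 1 + rho).
riccati_gain_oracle <- function(rho, P0 = 1000, tol = 1e-13,
                                max_iter = 2e6) {
  P <- P0
  K <- NA_real_
  for (i in seq_len(max_iter)) {
    M <- P + 1
    K <- M / (M + rho)
    P_new <- (1 - K) * M
    if (abs(P_new - P) < tol) return(K)
    P <- P_new
  }
  K
}

# Brute-force Bayesian filter on a discretized state space: Gaussian
# random-walk transition (unit variance) by dense convolution, Gaussian
# likelihood with variance rho, posterior mean by quadrature.
grid_filter_oracle <- function(y, rho, init_mean = y[1], init_var = 1e3,
                               pad = 25, n_grid = 4001) {
  g <- seq(min(y) - pad, max(y) + pad, length.out = n_grid)
  trans <- outer(g, g, function(to, from) dnorm(to, from, 1))
  post <- dnorm(g, init_mean, sqrt(init_var))
  post <- post / sum(post)
  means <- numeric(length(y))
  for (t in seq_along(y)) {
    prior <- as.vector(trans %*% post)
    prior <- prior / sum(prior)
    post <- prior * dnorm(y[t], g, sqrt(rho))
    post <- post / sum(post)
    means[t] <- sum(g * post)
  }
  means
}

# Plain-R recursion oracles for the deterministic dynamics.
activity_recursion_oracle <- function(A, tau_a, n, bin_s) {
  a <- numeric(n)
  prev <- 0
  for (t in seq_len(n)) {
    prev <- prev + (bin_s / tau_a) * (A - prev)
    a[t] <- prev
  }
  a
}

state_recursion_oracle <- function(c_hat, a, alpha, w_c, c_ref) {
  x <- numeric(length(c_hat))
  prev <- 0
  for (t in seq_along(c_hat)) {
    prev <- (1 - w_c) * (alpha * prev + (1 - alpha) * a[t]) +
      w_c * (c_hat[t] - c_ref)
    x[t] <- prev
  }
  x
}

# trapezoid capnogram with known plateau values, one cycle per plateau;
# each cycle ends in its trough (independent of generate_capnogram)
trapezoid_capnogram <- function(plateaus, period_s = 4, fs = 50,
                                trough = 0) {
  spb <- period_s * fs
  frac <- (seq_len(spb) - 1) / spb
  co2 <- unlist(lapply(plateaus, function(p) {
    seg <- numeric(spb)
    seg[frac < 0.25] <- trough + (p - trough) * frac[frac < 0.25] / 0.25
    seg[frac >= 0.25 & frac < 0.6] <- p
    idx <- frac >= 0.6 & frac < 0.85
    seg[idx] <- p - (p - trough) * (frac[idx] - 0.6) / 0.25
    seg[frac >= 0.85] <- trough
    seg
  }))
  capnogram(time_s = (seq_along(co2) - 1) / fs, co2_pct = co2)
}

expect_rel_error_lt <- function(est, truth, tol) {
  expect_lt(max(abs(est - truth) / abs(truth)), tol)
}
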