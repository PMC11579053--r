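#' Steady-state Kalman gain of the internal CO2 estimator
#'
#' For the scalar random-walk state-space model with process variance
#' `q = 1` and measurement variance equal to `rho`, the prior variance converges
#' to the fixed point `M = (1 + sqrt(1 + 4 rho)) / 2` of the Riccati
#' recursion, giving the steady-state gain `K = M / (M + rho)`. A gain near
#' 1 means sensory-dominated estimation, a gain near 0 prediction-dominated
#' estimation (approximately `1 / sqrt(rho)` for large `rho`).
#'
#' @param rho Measurement-to-process noise variance ratio(s), > 0.
#' @return Steady-state gain(s) in (0, 1]; strictly decreasing in `rho`.
#' @examples
#' steady_state_gain(2)  # 0.5
#' @export
steady_state_gain <- function(rho) {
  if (any(!is.finite(rho)) || any(rho <= 0)) stop_format("rho must be > 0")
  M <- (1 + sqrt(1 + 4 * rho)) / 2
  M / (M + rho)
}

#' Kalman-filter estimate of the internal CO2 concentration
#'
#' Runs the scalar Kalman filter encoding the internal representation that
#' CO2 changes slowly but randomly from one breath to the next (random-walk
#' dynamics with unit process variance) over a per-bin etCO2 series. Only
#' the variance ratio `rho` is identifiable from the filter's behaviour; by
#' default the filter starts diffusely (`init_var = 1e3`) at the first
#' observation, so the first estimate equals the first observation.
#'
#' @param etco2 Per-bin etCO2 observations (% CO2).
#' @param rho Measurement-to-process noise variance ratio, > 0.
#' @param init_mean Initial state mean; default first observation.
#' @param init_var Initial state variance (units of process variance).
#' @return List with `c_hat` (posterior means, % CO2) and `kgain`
#'   (per-bin Kalman gains in (0, 1]).
#' @export
kalman_filter <- function(etco2, rho, init_mean = etco2[1], init_var = 1e3) {
  if (length(etco2) < 1) stop_format("etco2 must be nonempty")
  if (any(!is.finite(etco2))) stop_format("etco2 contains non-finite values")
  if (!is.finite(rho) || rho <= 0) stop_format("rho must be > 0")
  if (init_var < 0) stop_format("init_var must be >= 0")
  kalman_core(as.numeric(etco2), rho, init_mean, init_var)
}

#' Build-up of the activity-context effect
#'
#' The activity context `A` (expected respiratory demand of the current
#' activity, constant throughout a session) exerts a perceptual effect that
#' builds up by first-order relaxation,
#' `a_t = a_{t-1} + (bin_s / tau_a) (A - a_{t-1})` with `a_0 = 0`, i.e.
#' `a_t = A (1 - (1 - bin_s / tau_a)^t)`. With the default
#' `tau_a = 40` s the effect saturates (>= 95% of `A`) after about two
#' minutes.
#'
#' @param A Activity-context level (respiratory-state units).
#' @param tau_a Time constant in seconds, > 0.
#' @param n_bins Number of bins to simulate.
#' @param bin_s Bin width in seconds.
#' @return Numeric vector `a_1, ..., a_n`, monotone toward `A`.
#' @export
activity_trajectory <- function(A, tau_a, n_bins, bin_s = 10) {
  if (tau_a <= 0) stop_format("tau_a must be > 0")
  if (n_bins < 1) stop_format("n_bins must be >= 1")
  if (bin_s >= tau_a) {
    warning("bin_s >= tau_a: discrete relaxation step overshoots",
            call. = FALSE)
  }
  A * (1 - (1 - bin_s / tau_a)^(seq_len(n_bins)))
}

#' Respiratory-state recursion
#'
#' The latent respiratory state summarizing gas-exchange disequilibrium.
#' Each bin, the state predicted from the last breath and the activity
#' effect, `alpha x_{t-1} + (1 - alpha) a_t`, is updated toward the sensory
#' term (the estimated CO2 as deviation from the setpoint `c_ref`) with
#' individual weight `w_c`:
#' `x_t = (1 - w_c)(alpha x_{t-1} + (1 - alpha) a_t) + w_c (c_hat_t - c_ref)`.
#' With `w_c` near 0 the state is dominated by prediction and activity
#' context; with `w_c = 1` it tracks the CO2 estimate directly. Variant
#' `no_activity` drops the activity effect (`A = 0`), `no_memory` the
#' dependence on the previous state (`alpha = 0`).
#'
#' @param c_hat Per-bin estimated CO2 (% CO2), e.g. from [kalman_filter()].
#' @param a Per-bin activity effect from [activity_trajectory()].
#' @param params A [model_params()].
#' @param variant `"full"`, `"no_activity"` or `"no_memory"`.
#' @return Numeric vector of respiratory states, same length as `c_hat`.
#' @export
respiratory_state <- function(c_hat, a, params, variant = "full") {
  if (length(c_hat) != length(a)) {
    stop_format("c_hat and a must have the same length")
  }
  p <- variant_params(params, variant)
  if (p$A == 0) a <- rep(0, length(a))
  state_core(as.numeric(c_hat), as.numeric(a), p$alpha, p$w_c, p$c_ref, p$x0)
}

#' Linear readout to the breathlessness rating scale
#'
#' Maps the respiratory state to a predicted breathlessness rating through
#' a linear transformation, clipped to the hard limits of the visual analog
#' scale: `b = min(max(gain * x + offset, 0), 100)`.
#'
#' @param x Respiratory-state series.
#' @param gain Rating units per respiratory-state unit.
#' @param offset Rating units.
#' @return Predicted ratings in \[0, 100\].
#' @export
readout <- function(x, gain, offset) {
  clip_rating(gain * x + offset)
}

# shared forward pass (plain list; used by forward_model, the fitter and
# the synthetic generator so there is exactly one model implementation)
forward_series <- function(etco2, params, variant = "full", bin_s = 10) {
  p <- variant_params(params, variant)
  kf <- kalman_core(as.numeric(etco2), p$rho, etco2[1], 1e3)
  n <- length(etco2)
  a <- if (p$A == 0) rep(0, n) else {
    p$a0 + (p$A - p$a0) * (1 - (1 - bin_s / p$tau_a)^(seq_len(n)))
  }
  x <- state_core(kf$c_hat, a, p$alpha, p$w_c, p$c_ref, p$x0)
  list(c_hat = kf$c_hat, kgain = kf$kgain, a = a, x = x,
       b_pred = clip_rating(p$gain * x + p$offset))
}

#' Forward simulation of the perceptual model
#'
#' Composes the full processing cascade — Kalman estimation of internal CO2,
#' activity-effect build-up, respiratory-state recursion and linear readout —
#' for a per-bin etCO2 series, returning every intermediate series.
#'
#' @param etco2 Per-bin etCO2 (% CO2), or an `experiment_trace`.
#' @param params A [model_params()].
#' @param variant `"full"`, `"no_activity"` or `"no_memory"`.
#' @param protocol An [rb_protocol()]; supplies the bin width and time axis.
#' @return A `data.frame` of class `latent_trajectory` with columns
#'   `time_s`, `c_hat`, `kgain`, `a`, `x`, `b_pred`.
#' @examples
#' p <- model_params(rho = 2, w_c = 0.5, A = 40, gain = 8, offset = 10)
#' et <- generate_co2_trace(profile_persistent())
#' traj <- forward_model(et, p)
#' range(traj$b_pred)
#' @export
forward_model <- function(etco2, params, variant = "full",
                          protocol = rb_protocol()) {
  variant <- check_variant(variant, allow_linear = FALSE)
  if (inherits(etco2, "experiment_trace")) {
    protocol <- trace_protocol(etco2)
    etco2 <- etco2$etco2_pct
  }
  fs <- forward_series(etco2, params, variant, protocol$bin_s)
  tt <- (seq_along(etco2) - 0.5) * protocol$bin_s
  structure(data.frame(time_s = tt, c_hat = fs$c_hat, kgain = fs$kgain,
                       a = fs$a, x = fs$x, b_pred = fs$b_pred),
            class = c("latent_trajectory", "data.frame"))
}
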