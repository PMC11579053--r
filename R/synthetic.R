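#' Virtual-participant profile
#'
#' Ground truth for one simulated rebreathing participant: the generating
#' model parameters and variant, the rating noise level, and the shape of
#' the session's CO2 trajectory (baseline level, linear rebreathing ramp,
#' exponential recovery, additive measurement noise). All generators are
#' pure functions of (profile, protocol, seed).
#'
#' CO2 defaults emulate the standard session: 5.2 % baseline, a ramp of
#' 0.9 %/min (about 7.5 % at end of rebreathing), recovery time constant
#' 30 s and 0.08 % measurement noise.
#'
#' @param name Profile label.
#' @param true_params A [model_params()].
#' @param variant Generating variant (`"full"`, `"no_activity"`,
#'   `"no_memory"`).
#' @param rating_noise_sd Rating noise SD (rating units, >= 0). Default 5.
#' @param baseline_pct Baseline etCO2 (% CO2), in \[3, 7\].
#' @param ramp_pct_per_min Rebreathing ramp slope (% CO2 per minute).
#' @param recovery_tau_s Recovery decay time constant (s).
#' @param noise_sd_pct CO2 measurement noise SD (% CO2).
#' @param seed Integer seed.
#' @return An object of class `synthetic_profile`.
#' @export
synthetic_profile <- function(name, true_params, variant = "full",
                              rating_noise_sd = 5, baseline_pct = 5.2,
                              ramp_pct_per_min = 0.9, recovery_tau_s = 30,
                              noise_sd_pct = 0.08, seed = 1) {
  variant <- check_variant(variant, allow_linear = FALSE)
  if (rating_noise_sd < 0) stop_format("rating_noise_sd must be >= 0")
  if (noise_sd_pct < 0) stop_format("noise_sd_pct must be >= 0")
  if (baseline_pct < 3 || baseline_pct > 7) {
    stop_format("baseline_pct must be in [3, 7] % CO2")
  }
  if (recovery_tau_s <= 0) stop_format("recovery_tau_s must be > 0")
  structure(list(name = name, true_params = true_params, variant = variant,
                 rating_noise_sd = rating_noise_sd,
                 baseline_pct = baseline_pct,
                 ramp_pct_per_min = ramp_pct_per_min,
                 recovery_tau_s = recovery_tau_s,
                 noise_sd_pct = noise_sd_pct, seed = as.integer(seed)),
            class = "synthetic_profile")
}

#' @export
print.synthetic_profile <- function(x, ...) {
  cat(sprintf("Synthetic profile '%s' (%s variant, seed %d)\n",
              x$name, x$variant, x$seed))
  cat(sprintf("  CO2: baseline %.2f%%, ramp %.2f%%/min, tau %.0fs, sd %.2f%%\n",
              x$baseline_pct, x$ramp_pct_per_min, x$recovery_tau_s,
              x$noise_sd_pct))
  cat(sprintf("  rating noise sd %.1f\n", x$rating_noise_sd))
  print(x$true_params)
  invisible(x)
}

#' Named heterogeneity profiles
#'
#' Three virtual-participant classes encoding the heterogeneity observed in
#' rebreathing studies: `sensory_dominated` (trusted CO2 sensing, ratings
#' track etCO2 and recover), `persistent` (prediction-dominated with a
#' strong activity context: ratings build up and stay high after etCO2 has
#' returned to baseline — the decoupled pattern), and `low_responder`
#' (weak readout, ratings stay low throughout).
#'
#' @param seed Integer seed.
#' @param rating_noise_sd Rating noise SD. Default 5.
#' @return A [synthetic_profile()].
#' @export
profile_sensory_dominated <- function(seed = 101, rating_noise_sd = 5) {
  synthetic_profile("sensory_dominated",
                    model_params(rho = 0.1, w_c = 0.9, A = 0,
                                 gain = 30, offset = 5),
                    variant = "full", rating_noise_sd = rating_noise_sd,
                    seed = seed)
}

#' @rdname profile_sensory_dominated
#' @export
profile_persistent <- function(seed = 102, rating_noise_sd = 5) {
  synthetic_profile("persistent",
                    model_params(rho = 100, w_c = 0.15, A = 60,
                                 gain = 1, offset = 5),
                    variant = "full", rating_noise_sd = rating_noise_sd,
                    seed = seed)
}

#' @rdname profile_sensory_dominated
#' @export
profile_low_responder <- function(seed = 103, rating_noise_sd = 5) {
  synthetic_profile("low_responder",
                    model_params(rho = 1, w_c = 0.4, A = 5,
                                 gain = 2, offset = 2),
                    variant = "full", rating_noise_sd = rating_noise_sd,
                    seed = seed)
}

# noise-free per-bin mean CO2 trajectory at the bin centers
co2_mean_curve <- function(profile, protocol) {
  tt <- bin_centers(protocol)
  t_reb <- protocol$baseline_s
  t_rec <- protocol$baseline_s + protocol$rebreathing_s
  peak_excess <- profile$ramp_pct_per_min * protocol$rebreathing_s / 60
  mu <- rep(profile$baseline_pct, length(tt))
  reb <- tt >= t_reb & tt < t_rec
  mu[reb] <- profile$baseline_pct +
    profile$ramp_pct_per_min * (tt[reb] - t_reb) / 60
  rec <- tt >= t_rec
  mu[rec] <- profile$baseline_pct +
    peak_excess * exp(-(tt[rec] - t_rec) / profile$recovery_tau_s)
  mu
}

#' Generate a per-bin etCO2 series for a session
#'
#' Baseline bins sit at `baseline_pct`; during rebreathing etCO2 rises
#' linearly at `ramp_pct_per_min`; during recovery it decays exponentially
#' back toward baseline with time constant `recovery_tau_s`. Additive
#' Gaussian measurement noise (`noise_sd_pct`) is applied and the result is
#' clipped at 0. Deterministic given `profile$seed`.
#'
#' @param profile A [synthetic_profile()].
#' @param protocol An [rb_protocol()].
#' @return Numeric vector of per-bin etCO2 (% CO2).
#' @export
generate_co2_trace <- function(profile, protocol = rb_protocol()) {
  mu <- co2_mean_curve(profile, protocol)
  if (profile$noise_sd_pct > 0) {
    noise <- with_seed(profile$seed,
                       rnorm(length(mu), 0, profile$noise_sd_pct))
    mu <- mu + noise
  }
  pmax(mu, 0)
}

#' Generate a raw 50 Hz capnogram with known end-tidal values
#'
#' Builds a trapezoid-wave capnogram fixture: one respiratory cycle per
#' target, with the expiratory plateau set exactly to that breath's target
#' etCO2 and the inspiratory trough at the inspired CO2 level (0 during
#' baseline/recovery, rising modestly during rebreathing, kept below the
#' detection threshold of [segment_breaths()]). Each cycle ends in its
#' trough, so segmentation recovers the plateau values exactly.
#'
#' @param etco2_targets Per-breath end-tidal targets (% CO2).
#' @param protocol An [rb_protocol()]; supplies the sampling rate and phase
#'   boundaries for the inspired-CO2 level.
#' @param breath_period_s Seconds per respiratory cycle.
#' @return A [capnogram()] spanning `length(etco2_targets) *
#'   breath_period_s` seconds.
#' @export
generate_capnogram <- function(etco2_targets, protocol = rb_protocol(),
                               breath_period_s = 4) {
  nb <- length(etco2_targets)
  if (nb == 0) stop_format("empty capnogram: no breaths requested")
  fs <- protocol$sample_rate_hz
  if (breath_period_s < 2 / fs) {
    stop_format("breath_period_s too short for the sampling rate")
  }
  spb <- round(breath_period_s * fs)       # samples per breath
  t_reb <- protocol$baseline_s
  t_rec <- protocol$baseline_s + protocol$rebreathing_s
  frac <- (seq_len(spb) - 1) / spb         # position within the cycle
  co2 <- numeric(nb * spb)
  for (b in seq_len(nb)) {
    t0 <- (b - 1) * breath_period_s
    plateau <- etco2_targets[b]
    insp <- if (t0 >= t_reb && t0 < t_rec) {
      # inspired CO2 rises through the rebreathing phase but stays well
      # below half the plateau so trough detection is unambiguous
      min(2, 0.35 * plateau) * (t0 - t_reb) / protocol$rebreathing_s
    } else 0
    seg <- numeric(spb)
    rise <- frac < 0.2
    plat <- frac >= 0.2 & frac < 0.55
    fall <- frac >= 0.55 & frac < 0.8
    trough <- frac >= 0.8
    seg[rise] <- insp + (plateau - insp) * frac[rise] / 0.2
    seg[plat] <- plateau
    seg[fall] <- plateau - (plateau - insp) * (frac[fall] - 0.55) / 0.25
    seg[trough] <- insp
    co2[(b - 1) * spb + seq_len(spb)] <- seg
  }
  capnogram(time_s = (seq_along(co2) - 1) / fs, co2_pct = co2)
}

#' Simulate a virtual participant
#'
#' Draws the session's etCO2 series from [generate_co2_trace()], runs the
#' generating model variant forward with the profile's true parameters
#' (the same implementation used everywhere in the package), adds Gaussian
#' rating noise and clips to \[0, 100\]. Deterministic given
#' `profile$seed`.
#'
#' @param profile A [synthetic_profile()].
#' @param protocol An [rb_protocol()].
#' @return List with `trace` (an [experiment_trace()]), `latent` (the
#'   noise-free `latent_trajectory` ground truth) and `profile`.
#' @export
generate_participant <- function(profile, protocol = rb_protocol()) {
  etco2 <- generate_co2_trace(profile, protocol)
  latent <- forward_model(etco2, profile$true_params, profile$variant,
                          protocol)
  rating <- latent$b_pred
  if (profile$rating_noise_sd > 0) {
    noise <- with_seed(profile$seed + 1L,
                       rnorm(length(rating), 0, profile$rating_noise_sd))
    rating <- clip_rating(rating + noise)
  }
  list(trace = experiment_trace(etco2, rating = rating, protocol = protocol),
       latent = latent, profile = profile)
}

#' Read or write a profile as JSON
#'
#' @param profile A [synthetic_profile()].
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  out <- unclass(profile)
  out$true_params <- unclass(out$true_params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- do.call(model_params,
                  x$true_params[intersect(names(formals(model_params)),
                                          names(x$true_params))])
  synthetic_profile(x$name, pars, variant = x$variant,
                    rating_noise_sd = x$rating_noise_sd,
                    baseline_pct = x$baseline_pct,
                    ramp_pct_per_min = x$ramp_pct_per_min,
                    recovery_tau_s = x$recovery_tau_s,
                    noise_sd_pct = x$noise_sd_pct, seed = x$seed)
}

#' Harness profiles for recovery and model-selection studies
#'
#' The generating profile used by the validation harness for each model
#' variant, chosen a priori for identifiability and distinguishability at
#' realistic noise levels: all three have a clear sensory component
#' (`rho = 2`, sensory weight around one half) and, where applicable, a
#' substantial activity context, so that removing either mechanism visibly
#' changes the predicted rating trajectory.
#'
#' @param variant Generating variant.
#' @param rating_noise_sd Rating noise SD. Default 5.
#' @param seed Integer seed.
#' @return A [synthetic_profile()].
#' @export
recovery_profile <- function(variant = c("full", "no_activity", "no_memory"),
                             rating_noise_sd = 5, seed = 1) {
  variant <- match.arg(variant)
  pars <- switch(variant,
    full = model_params(rho = 2, w_c = 0.5, A = 40, gain = 8, offset = 10),
    no_activity = model_params(rho = 2, w_c = 0.5, A = 0, gain = 12,
                               offset = 10),
    no_memory = model_params(rho = 2, w_c = 0.6, A = 8, gain = 10,
                             offset = 10))
  synthetic_profile(paste0("recovery_", variant), pars, variant = variant,
                    rating_noise_sd = rating_noise_sd, seed = seed)
}
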