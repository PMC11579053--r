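#' Parameters of the breathlessness perception model
#'
#' Bundles the five individually fitted (free) parameters of the perceptual
#' model with the structural constants shared across participants.
#'
#' Free parameters:
#' * `rho` — ratio of CO2 measurement-noise variance to the assumed
#'   random-walk process variance (dimensionless, > 0). Small `rho` means a
#'   trusted sensor (Kalman gain near 1, sensory-dominated perception);
#'   large `rho` means prediction-dominated perception.
#' * `w_c` — sensory update weight of the respiratory state in \[0, 1\]: how
#'   much the estimated CO2 level (as deviation from `c_ref`) is taken into
#'   account per bin, versus the prediction from the previous state and the
#'   activity context.
#' * `A` — activity-context level (respiratory-state units); its perceptual
#'   effect builds up with time constant `tau_a` and saturates at `A`.
#' * `gain`, `offset` — linear readout from respiratory state to the 0-100
#'   breathlessness rating.
#'
#' Structural constants (shared, configurable):
#' * `alpha` — respiratory-state persistence per bin (0 <= alpha < 1);
#'   default 0.8 per 10 s bin, i.e. a state memory of roughly 45 s.
#' * `tau_a` — activity-effect time constant in seconds; default 40 s so the
#'   effect has reached about 95% of `A` after two minutes.
#' * `c_ref` — CO2 reference level in % CO2; default 5.0, the initial CO2
#'   concentration of the rebreathing bag, serving as a physiologic setpoint
#'   proxy. CO2 enters the state as deviation from `c_ref`.
#' * `x0`, `a0` — initial respiratory state and activity effect (0).
#'
#' @param rho,w_c,A,gain,offset Free parameters (see Details).
#' @param alpha,tau_a,c_ref,x0,a0 Structural constants.
#' @return An object of class `model_params`.
#' @examples
#' model_params(rho = 2, w_c = 0.5, A = 40, gain = 8, offset = 10)
#' @export
model_params <- function(rho, w_c, A, gain, offset,
                         alpha = 0.8, tau_a = 40, c_ref = 5.0,
                         x0 = 0, a0 = 0) {
  if (rho <= 0) stop_format("rho must be > 0")
  if (w_c < 0 || w_c > 1) stop_format("w_c must be in [0, 1]")
  if (alpha < 0 || alpha >= 1) stop_format("alpha must be in [0, 1)")
  if (tau_a <= 0) stop_format("tau_a must be > 0")
  structure(list(rho = rho, w_c = w_c, A = A, gain = gain, offset = offset,
                 alpha = alpha, tau_a = tau_a, c_ref = c_ref,
                 x0 = x0, a0 = a0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Perceptual model parameters\n")
  cat(sprintf("  free:  rho=%.4g  w_c=%.4g  A=%.4g  gain=%.4g  offset=%.4g\n",
              x$rho, x$w_c, x$A, x$gain, x$offset))
  cat(sprintf("  fixed: alpha=%.3g  tau_a=%.3g s  c_ref=%.3g %%CO2\n",
              x$alpha, x$tau_a, x$c_ref))
  invisible(x)
}

#' Model variants
#'
#' The perceptual model is compared in four versions: the `full` model; a
#' `no_activity` variant with the activity context removed (`A = 0`, four
#' free parameters); a `no_memory` variant with the dependence on the
#' respiratory state in the last breath removed (`alpha = 0`, five free
#' parameters); and a `linear_regression` baseline in which breathlessness
#' is a scaled and shifted copy of measured CO2 (two free parameters).
#'
#' @return `model_variants()` returns the four variant names.
#' @export
model_variants <- function() {
  c("full", "no_activity", "no_memory", "linear_regression")
}

check_variant <- function(variant, allow_linear = TRUE) {
  variant <- match.arg(variant, model_variants())
  if (!allow_linear && variant == "linear_regression") {
    stop_format("variant 'linear_regression' has no latent state model")
  }
  variant
}

#' @rdname model_variants
#' @param params A [model_params()].
#' @param variant One of `"full"`, `"no_activity"`, `"no_memory"`.
#' @return `variant_params()` returns `params` with the variant's
#'   restriction applied.
#' @export
variant_params <- function(params, variant = "full") {
  variant <- check_variant(variant, allow_linear = FALSE)
  if (variant == "no_activity") params$A <- 0
  if (variant == "no_memory") params$alpha <- 0
  params
}

#' @rdname model_variants
#' @return `free_params()` returns the names of the variant's free
#'   parameters; `n_free_params()` their count (used as k in AIC).
#' @export
free_params <- function(variant = "full") {
  switch(check_variant(variant),
         full = c("rho", "w_c", "A", "gain", "offset"),
         no_activity = c("rho", "w_c", "gain", "offset"),
         no_memory = c("rho", "w_c", "A", "gain", "offset"),
         linear_regression = c("intercept", "slope"))
}

#' @rdname model_variants
#' @export
n_free_params <- function(variant = "full") {
  length(free_params(variant))
}

#' Read or write model parameters as JSON
#'
#' @param params A [model_params()].
#' @param path File path.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("rho", "w_c", "A", "gain", "offset")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop_format("parameter JSON missing field(s): ",
                paste(missing, collapse = ", "))
  }
  keep <- intersect(names(formals(model_params)), names(x))
  do.call(model_params, x[keep])
}
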