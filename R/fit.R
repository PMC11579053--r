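#' Options controlling model fitting
#'
#' The least-squares surface of the perceptual model is multimodal, so
#' fitting restarts a bounded Levenberg-Marquardt optimizer from
#' `n_starts` Latin-hypercube points spread over the parameter box
#' (deterministic given `seed`). `rho` is searched in log10 space by
#' default for conditioning.
#'
#' Default box constraints span all plausible rating-scale behaviours:
#' log10(rho) in \[-3, 4\], `w_c` in \[0, 1\], `A` in \[-100, 100\],
#' `gain` in \[0, 50\], `offset` in \[-100, 100\].
#'
#' @param n_starts Number of optimizer restarts (>= 1). Default 20.
#' @param seed Integer seed for start-point sampling.
#' @param log_rho Search `rho` as log10(rho)? Default `TRUE`.
#' @param bounds Named list of `c(lower, upper)` per free parameter
#'   (names `log10_rho` or `rho`, `w_c`, `A`, `gain`, `offset`).
#' @param maxiter,ftol,ptol Levenberg-Marquardt control (see
#'   [minpack.lm::nls.lm.control()]); tight tolerances by default so
#'   noise-free optima are located to high precision.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 20, seed = 1, log_rho = TRUE,
                        bounds = default_bounds(),
                        maxiter = 200, ftol = 1e-13, ptol = 1e-13) {
  if (n_starts < 1) stop_format("n_starts must be >= 1")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !(b[1] < b[2])) {
      stop_format("bounds for ", nm, " must be c(lower, upper), lower < upper")
    }
  }
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 log_rho = isTRUE(log_rho), bounds = bounds,
                 maxiter = maxiter, ftol = ftol, ptol = ptol),
            class = "fit_options")
}

#' @rdname fit_options
#' @export
default_bounds <- function() {
  list(log10_rho = c(-3, 4), rho = c(1e-3, 1e4), w_c = c(0, 1),
       A = c(-100, 100), gain = c(0, 50), offset = c(-100, 100))
}

# bounds matrix in optimizer space for one variant
variant_bounds <- function(variant, options) {
  nm <- free_params(variant)
  nm_opt <- if (options$log_rho) sub("^rho$", "log10_rho", nm) else nm
  b <- options$bounds
  lower <- vapply(nm_opt, function(k) b[[k]][1], numeric(1))
  upper <- vapply(nm_opt, function(k) b[[k]][2], numeric(1))
  list(names = nm, names_opt = nm_opt, lower = lower, upper = upper)
}

# optimizer-space vector -> model_params (no validation; hot path)
theta_to_params <- function(theta, variant, options, constants) {
  names(theta) <- NULL
  rho <- if (options$log_rho) 10^theta[1] else theta[1]
  if (variant == "no_activity") {
    p <- list(rho = rho, w_c = theta[2], A = 0, gain = theta[3],
              offset = theta[4])
  } else {
    p <- list(rho = rho, w_c = theta[2], A = theta[3], gain = theta[4],
              offset = theta[5])
  }
  structure(c(p, constants, list(x0 = 0, a0 = 0)), class = "model_params")
}

default_constants <- function() list(alpha = 0.8, tau_a = 40, c_ref = 5.0)

#' Fit the perceptual model to one participant's trace
#'
#' Estimates the variant's free parameters by minimizing the sum of squared
#' differences between observed and model-predicted breathlessness ratings
#' (bounded Levenberg-Marquardt with Latin-hypercube multi-start; bins with
#' missing ratings are excluded from the objective). The reported fit is the
#' restart with the lowest residual sum of squares; results are
#' deterministic given `options$seed`.
#'
#' @param trace An [experiment_trace()].
#' @param variant One of [model_variants()]; `"linear_regression"` is
#'   dispatched to [fit_linear()].
#' @param options A [fit_options()].
#' @param constants Structural constants shared across participants:
#'   list with `alpha`, `tau_a`, `c_ref`.
#' @return An object of class `fit_result`: list with `variant`, `params`
#'   (full [model_params()]), `estimates` (named free-parameter vector),
#'   `rss`, `n_obs`, `k_free`, `converged`, `start_rss` (RSS per restart).
#' @examples
#' sim <- generate_participant(profile_sensory_dominated())
#' fit <- fit_model(sim$trace, "full", fit_options(n_starts = 5))
#' fit$estimates
#' @export
fit_model <- function(trace, variant = "full", options = fit_options(),
                      constants = default_constants()) {
  variant <- check_variant(variant)
  if (variant == "linear_regression") return(fit_linear(trace))
  protocol <- trace_protocol(trace)
  obs <- which(!is.na(trace$rating))
  k <- n_free_params(variant)
  if (length(obs) < k + 2) {
    stop_format("too few observations: need at least ", k + 2,
                " non-missing ratings, have ", length(obs))
  }
  y <- trace$rating[obs]
  if (sd(y) == 0) {
    warning("all ratings identical: gain is unidentifiable", call. = FALSE)
  }
  etco2 <- trace$etco2_pct
  bin_s <- protocol$bin_s

  resid_fn <- function(theta) {
    p <- theta_to_params(theta, variant, options, constants)
    y - forward_series(etco2, p, variant, bin_s)$b_pred[obs]
  }

  vb <- variant_bounds(variant, options)
  # Latin-hypercube candidates over the box; start points whose initial
  # predictions are entirely clipped off the rating scale are discarded
  # (the clipped readout makes the objective locally flat there, which
  # stalls a gradient-based optimizer), keeping the first n_starts viable
  # candidates. Deterministic given the seed.
  cand <- with_seed(options$seed, lhs::randomLHS(10 * options$n_starts, k))
  cand <- sweep(cand, 2, vb$upper - vb$lower, "*")
  cand <- sweep(cand, 2, vb$lower, "+")
  viable <- apply(cand, 1, function(theta) {
    p <- theta_to_params(theta, variant, options, constants)
    b <- forward_series(etco2, p, variant, bin_s)$b_pred
    any(b > 0 & b < 100)
  })
  keep <- c(which(viable), which(!viable))[seq_len(options$n_starts)]
  starts <- cand[sort(keep), , drop = FALSE]

  ctrl <- minpack.lm::nls.lm.control(maxiter = options$maxiter,
                                     ftol = options$ftol,
                                     ptol = options$ptol)
  best <- NULL
  start_rss <- rep(NA_real_, options$n_starts)
  for (s in seq_len(options$n_starts)) {
    fit <- minpack.lm::nls.lm(par = starts[s, ], lower = vb$lower,
                              upper = vb$upper, fn = resid_fn,
                              control = ctrl)
    start_rss[s] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  theta <- as.numeric(best$par)
  params <- theta_to_params(theta, variant, options, constants)
  est <- setNames(unlist(params[free_params(variant)]), free_params(variant))
  structure(list(variant = variant, params = params, estimates = est,
                 rss = best$deviance, n_obs = length(obs), k_free = k,
                 converged = best$info %in% 1:4,
                 start_rss = start_rss, info = best$info,
                 message = best$message),
            class = "fit_result")
}

#' Linear-regression baseline fit
#'
#' Fits the baseline model in which breathlessness is a scaled and shifted
#' version of the sensory input, `b = beta0 + beta1 * etCO2 + error`, by
#' ordinary least squares on the non-missing rating bins.
#'
#' @param trace An [experiment_trace()].
#' @return A `fit_result` with `estimates` `intercept` and `slope`.
#' @export
fit_linear <- function(trace) {
  obs <- which(!is.na(trace$rating))
  if (length(obs) < 3) stop_format("need at least 3 non-missing ratings")
  x <- trace$etco2_pct[obs]
  y <- trace$rating[obs]
  if (sd(x) == 0) {
    stop_format("etCO2 is constant: linear regression is singular")
  }
  fit <- lm(y ~ x)
  est <- setNames(as.numeric(coef(fit)), c("intercept", "slope"))
  structure(list(variant = "linear_regression", params = NULL,
                 estimates = est, rss = sum(fit$residuals^2),
                 n_obs = length(obs), k_free = 2L, converged = TRUE,
                 start_rss = sum(fit$residuals^2), info = 0L,
                 message = "OLS closed form"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (%s): rss = %.6g over %d bins, k = %d%s\n",
              x$variant, x$rss, x$n_obs, x$k_free,
              if (x$converged) "" else " [not converged]"))
  print(round(x$estimates, 5))
  invisible(x)
}

#' Predicted ratings from a fit
#'
#' @param fit A `fit_result`.
#' @param trace The trace it was fitted to.
#' @return Per-bin predicted ratings.
#' @export
predict_ratings <- function(fit, trace) {
  if (fit$variant == "linear_regression") {
    # the baseline is defined unclipped, consistent with its OLS rss
    return(unname(fit$estimates["intercept"] +
                    fit$estimates["slope"] * trace$etco2_pct))
  }
  forward_model(trace, fit$params, fit$variant)$b_pred
}

#' Serialize a fit result as JSON
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @export
write_fit <- function(fit, path) {
  out <- list(variant = fit$variant, estimates = as.list(fit$estimates),
              rss = fit$rss, n_obs = fit$n_obs, k_free = fit$k_free,
              converged = fit$converged)
  if (!is.null(fit$params)) out$params <- unclass(fit$params)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
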