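#' Parameter-recovery experiment
#'
#' Validates the fitting procedure on data with known ground truth:
#' simulates `n_reps` virtual participants from `profile` (replicate `i`
#' uses seed `profile$seed + i`), fits the generating variant to each, and
#' aggregates truth-versus-estimate statistics per free parameter.
#' Deterministic given the profile and option seeds.
#'
#' @param profile A [synthetic_profile()].
#' @param n_reps Number of replicates (>= 1).
#' @param options A [fit_options()]; replicate `i` uses start seed
#'   `options$seed + i`.
#' @param protocol An [rb_protocol()].
#' @param constants Structural constants, as in [fit_model()].
#' @return An object of class `recovery_report`: list with `estimates`
#'   (replicate x parameter matrix), `truth`, `rss` and `summary` (per
#'   parameter: truth, bias, RMSE and 25/50/75% quantiles of the relative
#'   error, `NA` where the true value is 0).
#' @examples
#' prof <- profile_sensory_dominated(rating_noise_sd = 0)
#' rec <- recovery_experiment(prof, n_reps = 2, fit_options(n_starts = 5))
#' rec$summary
#' @export
recovery_experiment <- function(profile, n_reps, options = fit_options(),
                                protocol = rb_protocol(),
                                constants = default_constants()) {
  if (n_reps < 1) stop_format("n_reps must be >= 1")
  par_names <- free_params(profile$variant)
  truth <- setNames(unlist(profile$true_params[par_names]), par_names)
  est <- matrix(NA_real_, n_reps, length(par_names),
                dimnames = list(NULL, par_names))
  rss <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    prof_i <- profile
    prof_i$seed <- profile$seed + i
    sim <- generate_participant(prof_i, protocol)
    opt_i <- options
    opt_i$seed <- options$seed + i
    fit <- fit_model(sim$trace, profile$variant, options = opt_i,
                     constants = constants)
    est[i, ] <- fit$estimates[par_names]
    rss[i] <- fit$rss
  }
  err <- sweep(est, 2, truth, "-")
  rel <- sweep(abs(err), 2, abs(truth), "/")
  rel[, truth == 0] <- NA_real_
  qs <- vapply(seq_along(par_names), function(j) {
    if (truth[j] == 0) rep(NA_real_, 3)
    else quantile(rel[, j], probs = c(0.25, 0.5, 0.75), names = FALSE)
  }, numeric(3))
  summary <- data.frame(
    param = par_names,
    true = as.numeric(truth),
    bias = colMeans(err),
    rmse = sqrt(colMeans(err^2)),
    rel_err_q25 = qs[1, ],
    rel_err_q50 = qs[2, ],
    rel_err_q75 = qs[3, ],
    row.names = NULL)
  structure(list(profile = profile, n_reps = n_reps, estimates = est,
                 truth = truth, rss = rss, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: '%s' (%s), %d replicates\n",
              x$profile$name, x$profile$variant, x$n_reps))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Model-selection recovery experiment
#'
#' Simulates `n_reps` datasets from the profile's generating variant and
#' runs the four-way AIC comparison on each, tallying which model is
#' selected. Used to check that AIC recovers the generating variant and
#' that the linear-regression baseline does not win on data with genuine
#' state dynamics.
#'
#' @inheritParams recovery_experiment
#' @return An object of class `selection_report`: list with `selected`
#'   (winning variant per replicate), `counts` (table over variants),
#'   `accuracy` (fraction of replicates selecting the generating variant)
#'   and `generating` (the generating variant).
#' @export
selection_experiment <- function(profile, n_reps, options = fit_options(),
                                 protocol = rb_protocol(),
                                 constants = default_constants()) {
  if (n_reps < 1) stop_format("n_reps must be >= 1")
  selected <- character(n_reps)
  for (i in seq_len(n_reps)) {
    prof_i <- profile
    prof_i$seed <- profile$seed + i
    sim <- generate_participant(prof_i, protocol)
    opt_i <- options
    opt_i$seed <- options$seed + i
    tab <- compare_models(sim$trace, options = opt_i, constants = constants)
    selected[i] <- attr(tab, "best")
  }
  counts <- table(factor(selected, levels = model_variants()))
  structure(list(profile = profile, n_reps = n_reps, selected = selected,
                 counts = counts,
                 accuracy = mean(selected == profile$variant),
                 generating = profile$variant),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Model-selection recovery: generated by '%s', %d replicates\n",
              x$generating, x$n_reps))
  print(x$counts)
  cat(sprintf("Generating variant selected in %.0f%% of replicates\n",
              100 * x$accuracy))
  invisible(x)
}
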