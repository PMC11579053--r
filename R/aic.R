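#' Akaike Information Criterion for a least-squares fit
#'
#' Gaussian least-squares form: `AIC = n log(rss / n) + 2 (k + 1)` (natural
#' log), where the `+ 1` counts the residual-variance parameter uniformly
#' across models, so rankings are unaffected by the convention. Lower is
#' better.
#'
#' @param rss Residual sum of squares, > 0 (a perfect fit returns `-Inf`
#'   with a warning).
#' @param n_obs Number of fitted observations; must exceed `k_free + 2`.
#' @param k_free Number of fitted parameters.
#' @return The AIC value.
#' @examples
#' compute_aic(36, 36, 5)  # 12
#' @export
compute_aic <- function(rss, n_obs, k_free) {
  if (n_obs <= k_free + 2) {
    stop_format("n_obs must exceed k_free + 2 for a meaningful AIC")
  }
  if (rss < 0) stop_format("rss must be >= 0")
  if (rss == 0) {
    warning("perfect fit (rss = 0): AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * (k_free + 1)
}

#' Four-way model comparison for one participant
#'
#' Fits the full perceptual model, the two reduced variants (no activity
#' context; no dependence on the last respiratory state) and the
#' linear-regression baseline to the same non-missing rating bins with
#' shared options, and compares them by AIC. The best model has the lowest
#' AIC; exact ties are broken toward fewer parameters.
#'
#' @param trace An [experiment_trace()].
#' @param options A [fit_options()] shared by all variants.
#' @param constants Structural constants, as in [fit_model()].
#' @return A `data.frame` of class `comparison_table` with columns
#'   `variant`, `rss`, `n_obs`, `k_free`, `aic`, `delta_aic`, attribute
#'   `best` (the winning variant) and attribute `fits` (the four
#'   `fit_result`s).
#' @examples
#' sim <- generate_participant(profile_persistent())
#' tab <- compare_models(sim$trace, fit_options(n_starts = 5))
#' attr(tab, "best")
#' @export
compare_models <- function(trace, options = fit_options(),
                           constants = default_constants()) {
  variants <- model_variants()
  fits <- lapply(variants, function(v) {
    fit_model(trace, v, options = options, constants = constants)
  })
  names(fits) <- variants
  n_obs <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1) {
    stop_format("variants were fitted on different observation sets")
  }
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  k <- vapply(fits, `[[`, numeric(1), "k_free")
  aic <- mapply(function(r, n, kk) {
    withCallingHandlers(compute_aic(r, n, kk),
                        warning = function(w) invokeRestart("muffleWarning"))
  }, rss, n_obs, k)
  ord <- order(aic, k)        # ties broken toward fewer parameters
  best <- variants[ord[1]]
  tab <- data.frame(variant = variants, rss = rss, n_obs = n_obs,
                    k_free = as.integer(k), aic = aic,
                    delta_aic = aic - min(aic), row.names = NULL)
  structure(tab, best = best, fits = fits,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Model comparison (lower AIC is better)\n")
  print.data.frame(as.data.frame(x), digits = 6)
  cat("Best model:", attr(x, "best"), "\n")
  invisible(x)
}

#' Write a comparison table as CSV or JSON
#'
#' CSV columns are `variant,rss,k_free,aic,delta_aic`.
#'
#' @param table A `comparison_table`.
#' @param path File path; extension `.json` selects JSON.
#' @export
write_comparison <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- list(best = attr(table, "best"),
                models = as.data.frame(table))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  lines <- c("variant,rss,k_free,aic,delta_aic",
             sprintf("%s,%s,%d,%s,%s", table$variant, fmt_num(table$rss),
                     table$k_free, fmt_num(table$aic),
                     fmt_num(table$delta_aic)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
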