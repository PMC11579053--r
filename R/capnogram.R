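#' Raw capnogram trace
#'
#' A uniformly sampled CO2 concentration signal (% CO2) as produced by a
#' capnograph at the mouthpiece. Values are validated against a physiologic
#' guard range of 0-15 % CO2 and the sampling must be strictly increasing
#' and uniform.
#'
#' @param time_s Sample times in seconds, uniformly spaced.
#' @param co2_pct CO2 concentration per sample (% CO2).
#'
#' @return A `data.frame` of class `capnogram` with columns `time_s`,
#'   `co2_pct` and attribute `sample_rate_hz`.
#' @export
capnogram <- function(time_s, co2_pct) {
  if (length(time_s) != length(co2_pct)) {
    stop_format("time_s and co2_pct must have the same length")
  }
  if (length(time_s) < 2) stop_format("capnogram needs at least 2 samples")
  dt <- diff(time_s)
  if (any(dt <= 0)) stop_format("time_s must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop_format("non-uniform sampling: capnogram must be on a regular grid")
  }
  if (any(!is.finite(co2_pct)) || any(co2_pct < 0) || any(co2_pct > 15)) {
    stop_format("co2_pct must be finite and within [0, 15] % CO2")
  }
  structure(data.frame(time_s = time_s, co2_pct = co2_pct),
            sample_rate_hz = 1 / stats::median(dt),
            class = c("capnogram", "data.frame"))
}

#' Segment a capnogram into single breaths
#'
#' Detects respiratory cycles in a capnogram and extracts the end-tidal CO2
#' (etCO2) of each breath as the maximum CO2 concentration within its
#' expiratory segment. A breath is closed when the signal falls below
#' `trough_frac` times the running peak of the current cycle (the
#' inspiratory trough); the detector then re-arms once the signal rises back
#' above that threshold. This assumes, as in real rebreathing recordings,
#' that end-tidal values change slowly from breath to breath relative to the
#' expiratory/inspiratory swing.
#'
#' @param cap A [capnogram()].
#' @param trough_frac Fraction of the running cycle peak below which the
#'   signal is considered inspiratory, in (0, 1). Default 0.5.
#'
#' @return A `data.frame` of class `breath_series` with columns
#'   `breath_end_time_s` and `etco2_pct`, one row per detected breath.
#' @export
segment_breaths <- function(cap, trough_frac = 0.5) {
  if (!inherits(cap, "capnogram")) cap <- capnogram(cap$time_s, cap$co2_pct)
  if (!(trough_frac > 0 && trough_frac < 1)) {
    stop_format("trough_frac must be in (0, 1)")
  }
  v <- cap$co2_pct
  tt <- cap$time_s
  n <- length(v)
  ends <- integer(0)
  ets <- numeric(0)
  state <- "expire"        # tracking a cycle's rise/plateau
  peak <- v[1]
  for (i in 2:n) {
    if (state == "expire") {
      if (v[i] > peak) peak <- v[i]
      if (peak > 0 && v[i] < trough_frac * peak) {
        ends <- c(ends, i)
        ets <- c(ets, peak)
        state <- "trough"
      }
    } else {                # in inspiratory trough; re-arm above threshold
      if (v[i] >= trough_frac * peak) {
        state <- "expire"
        peak <- v[i]
      }
    }
  }
  if (length(ends) == 0L) stop_format("no breaths detected")
  structure(data.frame(breath_end_time_s = tt[ends], etco2_pct = ets),
            class = c("breath_series", "data.frame"))
}

#' Average per-breath etCO2 onto the protocol bin grid
#'
#' Each bin's value is the arithmetic mean of the end-tidal CO2 of breaths
#' whose end time falls in the half-open interval `[bin_start, bin_end)`.
#' A bin containing no breath inherits the previous bin's value; the first
#' bin must contain at least one breath.
#'
#' @param breaths A `breath_series` from [segment_breaths()].
#' @param protocol An [rb_protocol()].
#'
#' @return Numeric vector of per-bin etCO2 (% CO2), length `n_bins(protocol)`.
#' @export
bin_to_grid <- function(breaths, protocol = rb_protocol()) {
  if (nrow(breaths) == 0) stop_format("no breaths to bin")
  tend <- breaths$breath_end_time_s
  total <- total_duration(protocol)
  if (any(tend < 0) || any(tend > total)) {
    stop_format("breath end times outside protocol span")
  }
  nb <- n_bins(protocol)
  idx <- pmin(floor(tend / protocol$bin_s) + 1L, nb)
  out <- rep(NA_real_, nb)
  means <- tapply(breaths$etco2_pct, idx, mean)
  out[as.integer(names(means))] <- as.numeric(means)
  if (is.na(out[1])) stop_format("cannot initialize grid: first bin is empty")
  for (k in seq_len(nb)[-1]) if (is.na(out[k])) out[k] <- out[k - 1]
  out
}
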