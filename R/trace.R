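#' One participant's binned rebreathing series
#'
#' The observed series for one rebreathing session on the rating grid:
#' bin-center time, protocol phase, binned end-tidal CO2 and the 0-100
#' breathlessness rating (missing ratings allowed for individual bins).
#'
#' @param etco2_pct Per-bin end-tidal CO2 (% CO2), length `n_bins(protocol)`.
#' @param rating Per-bin breathlessness rating in \[0, 100\] (visual analog
#'   scale; real-valued, `NA` allowed). Recycled if length 1.
#' @param protocol An [rb_protocol()].
#'
#' @return A `data.frame` of class `experiment_trace` with columns `time_s`,
#'   `phase`, `etco2_pct`, `rating` and attribute `protocol`.
#' @export
experiment_trace <- function(etco2_pct, rating = NA_real_,
                             protocol = rb_protocol()) {
  nb <- n_bins(protocol)
  if (length(etco2_pct) != nb) {
    stop_format("etco2_pct must have length n_bins(protocol) = ", nb)
  }
  if (length(rating) == 1L) rating <- rep(as.numeric(rating), nb)
  if (length(rating) != nb) {
    stop_format("rating must have length 1 or n_bins(protocol) = ", nb)
  }
  if (any(!is.finite(etco2_pct)) || any(etco2_pct < 0)) {
    stop_format("etco2_pct must be finite and >= 0")
  }
  bad <- !is.na(rating) & (rating < 0 | rating > 100)
  if (any(bad)) {
    stop_format("rating outside [0, 100] at bin(s) ",
                paste(which(bad), collapse = ", "))
  }
  structure(data.frame(time_s = bin_centers(protocol),
                       phase = phase_labels(protocol),
                       etco2_pct = as.numeric(etco2_pct),
                       rating = as.numeric(rating)),
            protocol = protocol,
            class = c("experiment_trace", "data.frame"))
}

#' @export
print.experiment_trace <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("Rebreathing trace: %d bins of %g s, %d rated\n",
              nrow(x), p$bin_s, sum(!is.na(x$rating))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

trace_protocol <- function(trace) {
  p <- attr(trace, "protocol")
  if (is.null(p)) rb_protocol() else p
}

#' Read and write trace files
#'
#' Trace files are UTF-8 CSV with a header and columns
#' `time_s,phase,etco2_pct,rating` (`phase` optional on input; empty `rating`
#' fields mean missing). `read_trace` also accepts a raw capnogram CSV with
#' columns `time_s,co2_pct`, which is reduced to the bin grid via
#' [segment_breaths()] and [bin_to_grid()] (ratings then all missing).
#' Writing uses full (17 significant digit) precision so a write/read
#' round trip reproduces finite values bit-exactly. Any further columns
#' (e.g. pulse oximetry or flow channels) are ignored.
#'
#' @param path CSV file path.
#' @param protocol An [rb_protocol()] describing the session timing.
#' @param trough_frac Breath-detection threshold passed to
#'   [segment_breaths()] when reading a raw capnogram file.
#' @param trace An `experiment_trace`.
#'
#' @return `read_trace` returns an `experiment_trace`; `write_trace`
#'   invisibly returns `path`.
#' @export
read_trace <- function(path, protocol = rb_protocol(), trough_frac = 0.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("time_s", "co2_pct") %in% names(df))) {
    cap <- capnogram(df$time_s, df$co2_pct)
    breaths <- segment_breaths(cap, trough_frac = trough_frac)
    return(experiment_trace(bin_to_grid(breaths, protocol),
                            rating = NA_real_, protocol = protocol))
  }
  for (col in c("time_s", "etco2_pct")) {
    if (!col %in% names(df)) {
      stop_format("trace file is missing mandatory column '", col, "'")
    }
  }
  rating <- if ("rating" %in% names(df)) as.numeric(df$rating) else NA_real_
  experiment_trace(df$etco2_pct, rating = rating, protocol = protocol)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  lines <- c("time_s,phase,etco2_pct,rating",
             sprintf("%s,%s,%s,%s",
                     fmt_num(trace$time_s), trace$phase,
                     fmt_num(trace$etco2_pct), fmt_num(trace$rating)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a latent trajectory as CSV
#'
#' Writes the per-bin internal series of a fitted or simulated model
#' (columns `time_s,c_hat,kgain,a,x,b_pred`) at full precision.
#'
#' @param latent A `latent_trajectory` from [forward_model()].
#' @param path CSV file path.
#' @export
write_latent <- function(latent, path) {
  cols <- c("time_s", "c_hat", "kgain", "a", "x", "b_pred")
  body <- do.call(paste, c(lapply(cols, function(cl) fmt_num(latent[[cl]])),
                           sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), path, useBytes = TRUE)
  invisible(path)
}
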