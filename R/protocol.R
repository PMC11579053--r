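#' Rebreathing protocol definition
#'
#' Describes the timing of a CO2 rebreathing session: a room-air baseline,
#' a rebreathing phase during which inhaled CO2 rises, and a room-air
#' recovery phase. Breathlessness is rated and end-tidal CO2 is binned on a
#' common grid of `bin_s` seconds; raw capnogram traces are sampled at
#' `sample_rate_hz`. The default instance is the standard protocol:
#' 60 s baseline, 150 s rebreathing, 150 s recovery, 10 s bins, 50 Hz.
#'
#' @param baseline_s Baseline (room air) duration in seconds.
#' @param rebreathing_s Rebreathing duration in seconds.
#' @param recovery_s Recovery (room air) duration in seconds.
#' @param bin_s Rating/binning interval in seconds.
#' @param sample_rate_hz Sampling rate of the raw capnogram in Hz.
#'
#' @return An object of class `rb_protocol`.
#' @examples
#' p <- rb_protocol()
#' n_bins(p)      # 36
#' @export
rb_protocol <- function(baseline_s = 60, rebreathing_s = 150,
                        recovery_s = 150, bin_s = 10, sample_rate_hz = 50) {
  durs <- c(baseline_s = baseline_s, rebreathing_s = rebreathing_s,
            recovery_s = recovery_s)
  if (bin_s <= 0) stop_format("bin_s must be > 0")
  if (sample_rate_hz <= 0) stop_format("sample_rate_hz must be > 0")
  if (any(durs <= 0)) stop_format("all phase durations must be > 0")
  if (any(abs(durs / bin_s - round(durs / bin_s)) > 1e-9)) {
    stop_format("phase durations must be integer multiples of bin_s")
  }
  structure(list(baseline_s = baseline_s, rebreathing_s = rebreathing_s,
                 recovery_s = recovery_s, bin_s = bin_s,
                 sample_rate_hz = sample_rate_hz),
            class = "rb_protocol")
}

#' @rdname rb_protocol
#' @param protocol An `rb_protocol` object.
#' @export
total_duration <- function(protocol) {
  protocol$baseline_s + protocol$rebreathing_s + protocol$recovery_s
}

#' @rdname rb_protocol
#' @export
n_bins <- function(protocol) {
  as.integer(round(total_duration(protocol) / protocol$bin_s))
}

#' @rdname rb_protocol
#' @export
bin_centers <- function(protocol) {
  (seq_len(n_bins(protocol)) - 0.5) * protocol$bin_s
}

#' @rdname rb_protocol
#' @export
phase_labels <- function(protocol) {
  ctr <- bin_centers(protocol)
  ifelse(ctr < protocol$baseline_s, "baseline",
         ifelse(ctr < protocol$baseline_s + protocol$rebreathing_s,
                "rebreathing", "recovery"))
}

#' @export
print.rb_protocol <- function(x, ...) {
  cat(sprintf(
    "Rebreathing protocol: %gs baseline + %gs rebreathing + %gs recovery\n",
    x$baseline_s, x$rebreathing_s, x$recovery_s))
  cat(sprintf("  %g s bins (%d bins), capnogram at %g Hz\n",
              x$bin_s, n_bins(x), x$sample_rate_hz))
  invisible(x)
}

#' Read or write a protocol as JSON
#'
#' @param protocol An `rb_protocol`.
#' @param path File path.
#' @return `read_protocol` returns an `rb_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("baseline_s", "rebreathing_s", "recovery_s", "bin_s",
              "sample_rate_hz")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop_format("protocol JSON missing field(s): ",
                paste(missing, collapse = ", "))
  }
  do.call(rb_protocol, x[needed])
}
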