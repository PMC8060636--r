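# Core containers: uniformly sampled signals and beat (inter-beat interval)
# series. These are deliberately plain S3 lists so every pipeline stage can
# construct and inspect them cheaply.

#' Uniformly sampled signal
#'
#' Container for a uniformly sampled 1-D signal. The time of sample `i`
#' (0-based) is `t0 + i / fs` seconds from record start.
#'
#' @param values numeric vector of samples (mV for PPG, mmHg for blood
#'   pressure, g for accelerometer axes)
#' @param fs sampling rate in Hz, must be > 0
#' @param t0 time of the first sample in seconds (default 0)
#' @param unit optional unit label carried along for bookkeeping
#'
#' @return an object of class `sampled_signal` with fields `values`, `fs`,
#'   `t0`, `unit`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 1 * (0:999) / 100), fs = 100)
#' signal_duration(s)
sampled_signal <- function(values, fs, t0 = 0, unit = NA_character_) {
  check_that(is.numeric(fs) && length(fs) == 1L && fs > 0, "fs must be a positive scalar (Hz)")
  check_that(is.numeric(t0) && length(t0) == 1L && is.finite(t0), "t0 must be a finite scalar (s)")
  values <- as.numeric(values)
  check_that(all(is.finite(values)), "signal values must be finite")
  structure(list(values = values, fs = fs, t0 = t0, unit = unit),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz, t0 = %g s (%.3f s)%s\n",
              length(x$values), x$fs, x$t0, signal_duration(x),
              if (is.na(x$unit)) "" else paste0(", unit ", x$unit)))
  invisible(x)
}

#' Sample times of a sampled signal
#'
#' @param sig a [sampled_signal()]
#' @return numeric vector of times in seconds from record start
#' @export
signal_times <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1) / sig$fs
}

#' Duration of a sampled signal in seconds
#' @param sig a [sampled_signal()]
#' @export
signal_duration <- function(sig) {
  if (length(sig$values) == 0L) return(0)
  (length(sig$values) - 1) / sig$fs
}

#' Extract a time window from a sampled signal
#'
#' @param sig a [sampled_signal()]
#' @param t_start,t_end window bounds in seconds from record start; clamped to
#'   the recorded extent
#' @return a [sampled_signal()] whose `t0` is the time of its first sample
#' @export
signal_window <- function(sig, t_start, t_end) {
  check_that(t_end > t_start, "t_end must exceed t_start")
  t <- signal_times(sig)
  keep <- t >= t_start - 1e-9 & t <= t_end + 1e-9
  check_that(any(keep), "requested window contains no samples")
  sampled_signal(sig$values[keep], sig$fs, t0 = t[which(keep)[1]], unit = sig$unit)
}

#' Inter-beat interval series with quality flags
#'
#' Raw RR / inter-beat intervals as exported by a beat-detecting device, with a
#' per-interval quality flag. Beat times are the cumulative sums of the
#' intervals, starting at 0.
#'
#' @param intervals_ms positive inter-beat intervals in ms
#' @param label posture/context tag: "supine", "standing", "night" or
#'   "unspecified"
#' @param flags per-interval quality mark, one of "normal", "ectopic",
#'   "missing", "artifact"; defaults to all "normal"
#' @return an object of class `beat_series`
#' @export
beat_series <- function(intervals_ms, label = "unspecified",
                        flags = rep("normal", length(intervals_ms))) {
  intervals_ms <- as.numeric(intervals_ms)
  check_that(all(is.finite(intervals_ms)) && all(intervals_ms > 0),
             "inter-beat intervals must be positive and finite (ms)")
  check_that(length(flags) == length(intervals_ms),
             "flags must have one entry per interval")
  check_that(all(flags %in% c("normal", "ectopic", "missing", "artifact")),
             "unknown flag value")
  check_that(label %in% c("supine", "standing", "night", "unspecified"),
             "label must be one of supine/standing/night/unspecified")
  structure(list(intervals_ms = intervals_ms, label = label, flags = flags),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d intervals (%s), %d flagged, mean %.1f ms\n",
              length(x$intervals_ms), x$label, sum(x$flags != "normal"),
              mean(x$intervals_ms)))
  invisible(x)
}

#' Normal-to-normal interval series
#'
#' Cleaned NN intervals ready for HRV analysis, carrying the number of
#' intervals that were replaced by interpolation.
#'
#' @param nn_ms positive NN intervals in ms
#' @param n_corrected number of intervals replaced during cleaning
#' @param source_label posture/context tag inherited from the raw series
#' @return an object of class `nn_series`
#' @export
nn_series <- function(nn_ms, n_corrected = 0L, source_label = "unspecified") {
  nn_ms <- as.numeric(nn_ms)
  check_that(all(is.finite(nn_ms)) && all(nn_ms > 0), "NN intervals must be positive")
  check_that(n_corrected >= 0 && n_corrected <= length(nn_ms),
             "n_corrected out of range")
  structure(list(nn_ms = nn_ms, n_corrected = as.integer(n_corrected),
                 corrected_fraction = if (length(nn_ms)) n_corrected / length(nn_ms) else 0,
                 source_label = source_label),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d NN intervals (%s), %d corrected (%.1f%%)\n",
              length(x$nn_ms), x$source_label, x$n_corrected,
              100 * x$corrected_fraction))
  invisible(x)
}

# Coerce a beat_series or plain vector into NN intervals (internal)
as_nn <- function(x) {
  if (inherits(x, "nn_series")) return(x)
  if (inherits(x, "beat_series")) return(nn_series(x$intervals_ms, 0L, x$label))
  nn_series(as.numeric(x))
}
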