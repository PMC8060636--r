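# Raw inter-beat interval series -> normal-to-normal (NN) series:
# ectopic / artifact detection against a local median reference, then
# cubic-spline interpolation over the flagged beats.

#' Flag ectopic / artifactual intervals against a local median
#'
#' Interval `i` is flagged "ectopic" when its relative deviation from the
#' median of its 10 nearest neighbours (5 on each side, truncated at the
#' edges) exceeds `rel_threshold`. Neighbours already carrying a non-normal
#' flag in the input are excluded from the reference; flags are assigned in a
#' single pass against the input flags. Existing flags are preserved.
#'
#' @param beats a [beat_series()] of at least 11 intervals
#' @param rel_threshold relative deviation threshold, in (0, 1); default 0.30
#' @return the [beat_series()] with updated flags
#' @export
#' @examples
#' b <- beat_series(c(rep(800, 10), 480, rep(800, 10)))
#' which(flag_artifacts(b)$flags == "ectopic")
flag_artifacts <- function(beats, rel_threshold = 0.30) {
  check_that(inherits(beats, "beat_series"), "beats must be a beat_series")
  check_that(rel_threshold > 0 && rel_threshold < 1, "rel_threshold must be in (0, 1)")
  rr <- beats$intervals_ms
  n <- length(rr)
  if (n < 11L) {
    sc_abort("series shorter than 11 intervals: too short for a local reference, pass through unflagged",
             "sc_validation_error")
  }
  usable <- beats$flags == "normal"
  flags <- beats$flags
  for (i in seq_len(n)) {
    left <- which(usable[seq_len(i - 1L)])
    left <- utils::tail(left, 5L)
    right_rel <- which(usable[seq.int(i + 1L, length.out = n - i)])
    right <- utils::head(i + right_rel, 5L)
    ref <- rr[c(left, right)]
    if (length(ref) == 0L) next
    m <- stats::median(ref)
    if (abs(rr[i] - m) / m > rel_threshold && flags[i] == "normal") {
      flags[i] <- "ectopic"
    }
  }
  beat_series(rr, label = beats$label, flags = flags)
}

#' Interpolate flagged intervals to obtain an NN series
#'
#' Flagged intervals are replaced by a cubic spline fitted to the unflagged
#' (interval value vs. beat index) points; series length is preserved, so
#' cumulative timing stays consistent for subsequent resampling. Segments
#' with 20% or more flagged beats are rejected rather than repaired.
#'
#' @param beats a flagged [beat_series()]
#' @param max_corrected_fraction rejection threshold on the flagged fraction
#'   (default 0.20)
#' @return an [nn_series()] with `n_corrected` set to the number of replaced
#'   intervals
#' @export
interpolate_nn <- function(beats, max_corrected_fraction = 0.20) {
  check_that(inherits(beats, "beat_series"), "beats must be a beat_series")
  rr <- beats$intervals_ms
  bad <- beats$flags != "normal"
  if (!any(bad)) return(nn_series(rr, 0L, beats$label))
  frac <- mean(bad)
  if (frac >= max_corrected_fraction) {
    sc_abort(sprintf("%.1f%% of beats flagged (>= %.0f%%): segment rejected",
                     100 * frac, 100 * max_corrected_fraction),
             "sc_quality_error")
  }
  idx <- seq_along(rr)
  check_that(sum(!bad) >= 4L, "too few clean beats to fit a spline")
  fit <- stats::splinefun(idx[!bad], rr[!bad], method = "fmm")
  nn <- rr
  nn[bad] <- fit(idx[bad])
  check_that(all(nn > 0), "interpolation produced non-positive intervals")
  nn_series(nn, sum(bad), beats$label)
}

#' Clean a raw interval series end to end
#'
#' Convenience wrapper: [flag_artifacts()] then [interpolate_nn()].
#'
#' @param beats a [beat_series()]
#' @param rel_threshold see [flag_artifacts()]
#' @param max_corrected_fraction see [interpolate_nn()]
#' @return an [nn_series()]
#' @export
clean_beats <- function(beats, rel_threshold = 0.30, max_corrected_fraction = 0.20) {
  interpolate_nn(flag_artifacts(beats, rel_threshold), max_corrected_fraction)
}
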