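# Sequence-method baroreflex sensitivity (BRS) from continuous blood
# pressure: per-beat systolic pressure and inter-beat interval extraction,
# detection of concordant monotone SBP-IBI runs, and the mean regression
# slope (ms/mmHg) over validated sequences.

# default sequence-validation thresholds
brs_defaults <- function() {
  list(min_dsbp_mmhg = 1, min_dibi_ms = 5, min_len = 3L, min_r = 0.85,
       min_sequences = 5L, lag_beats = 0L, refractory_s = 0.3, height_frac = 0.5)
}

#' Extract per-beat SBP and IBI from a blood pressure signal
#'
#' Systolic peaks are located as local maxima exceeding a relative height
#' threshold (`height_frac` of the amplitude range above the low quantile),
#' with a refractory period of `refractory_s` between accepted peaks. SBP is
#' the peak amplitude; IBI_n is the time from peak n to peak n+1 (ms), paired
#' with SBP_n.
#'
#' @param bp a [sampled_signal()] in mmHg, fs >= 100 Hz, duration >= 10 s
#' @param refractory_s minimum separation between systolic peaks (s)
#' @param height_frac fraction of the 2-98% amplitude range a peak must reach
#' @return a `beat_pressure_series`: `sbp_mmhg`, `ibi_ms`, `beat_times_s`
#' @export
extract_beats <- function(bp, refractory_s = 0.3, height_frac = 0.5) {
  check_that(inherits(bp, "sampled_signal"), "bp must be a sampled_signal")
  check_that(bp$fs >= 100, "need fs >= 100 Hz for beat timing")
  check_that(signal_duration(bp) >= 10, "need at least 10 s of signal")
  x <- bp$values
  q <- stats::quantile(x, c(0.02, 0.98), names = FALSE)
  if (diff(q) < 1e-3) sc_abort("no pulsatility in blood pressure signal", "sc_quality_error")
  thr <- q[1] + height_frac * diff(q)
  peaks <- local_maxima(x)
  peaks <- peaks[x[peaks] >= thr]
  if (length(peaks) < 3L) sc_abort("no systolic peaks found", "sc_quality_error")
  # enforce refractory: greedy by descending amplitude
  ord <- peaks[order(-x[peaks])]
  min_gap <- round(refractory_s * bp$fs)
  keep <- logical(0); kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  tpk <- bp$t0 + (kept - 1) / bp$fs
  m <- length(kept)
  structure(list(sbp_mmhg = x[kept][-m],
                 ibi_ms = diff(tpk) * 1000,
                 beat_times_s = tpk[-m]),
            class = "beat_pressure_series")
}

#' @export
print.beat_pressure_series <- function(x, ...) {
  cat(sprintf("<beat_pressure_series> %d beats, SBP %.0f-%.0f mmHg, IBI %.0f-%.0f ms\n",
              length(x$sbp_mmhg), min(x$sbp_mmhg), max(x$sbp_mmhg),
              min(x$ibi_ms), max(x$ibi_ms)))
  invisible(x)
}

#' Detect spontaneous baroreflex sequences
#'
#' A candidate sequence is a maximal run of at least `min_len` consecutive
#' beats in which SBP changes monotonically with per-step |dSBP| >=
#' `min_dsbp_mmhg` AND IBI changes monotonically in the same direction with
#' per-step |dIBI| >= `min_dibi_ms`. Candidates whose SBP-IBI Pearson
#' correlation reaches `min_r` are validated and returned with the
#' least-squares slope of IBI on SBP (ms/mmHg).
#'
#' @param beats a `beat_pressure_series` (see [extract_beats()]), or any list
#'   with `sbp_mmhg` and `ibi_ms`
#' @param min_dsbp_mmhg minimal per-step SBP change (mmHg)
#' @param min_dibi_ms minimal per-step IBI change (ms)
#' @param min_len minimal run length in beats
#' @param min_r minimal Pearson correlation
#' @param lag_beats IBI lag relative to SBP in beats (0 = same-beat pairing)
#' @return data.frame with one row per validated sequence: `start_index`,
#'   `length_beats`, `direction`, `slope_ms_per_mmhg`, `r`
#' @export
detect_sequences <- function(beats, min_dsbp_mmhg = 1, min_dibi_ms = 5,
                             min_len = 3L, min_r = 0.85, lag_beats = 0L) {
  sbp <- beats$sbp_mmhg
  ibi <- beats$ibi_ms
  if (lag_beats > 0L) {
    sbp <- sbp[seq_len(length(sbp) - lag_beats)]
    ibi <- ibi[-seq_len(lag_beats)]
  }
  n <- length(sbp)
  empty <- data.frame(start_index = integer(0), length_beats = integer(0),
                      direction = character(0), slope_ms_per_mmhg = numeric(0),
                      r = numeric(0))
  if (n < min_len) return(empty)
  ds <- diff(sbp); di <- diff(ibi)
  step_dir <- ifelse(ds >= min_dsbp_mmhg & di >= min_dibi_ms, 1L,
              ifelse(ds <= -min_dsbp_mmhg & di <= -min_dibi_ms, -1L, 0L))
  out <- list()
  r <- rle(step_dir)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0L) next
    len_steps <- r$lengths[k]
    if (len_steps + 1L < min_len) next
    i0 <- starts[k]; i1 <- ends[k] + 1L   # beats i0..i1
    s <- sbp[i0:i1]; v <- ibi[i0:i1]
    rr <- suppressWarnings(stats::cor(s, v))
    if (!is.finite(rr) || rr < min_r) next
    slope <- stats::cov(s, v) / stats::var(s)
    out[[length(out) + 1L]] <- data.frame(
      start_index = i0, length_beats = i1 - i0 + 1L,
      direction = if (r$values[k] > 0) "up" else "down",
      slope_ms_per_mmhg = slope, r = rr)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Estimate baroreflex sensitivity (sequence method)
#'
#' Runs [detect_sequences()] with the standard thresholds (1 mmHg, 5 ms,
#' >= 3 beats, r >= 0.85); the estimate is validated when at least
#' `min_sequences` (default 5) sequences are found, and equals the
#' unweighted mean of the validated slopes. Recordings shorter than 10 min
#' are processed but flagged.
#'
#' @param beats a `beat_pressure_series`
#' @param config optional overrides of the `brs_defaults()` thresholds
#' @return a `brs_estimate`: `brs_ms_per_mmhg` (NA when not valid),
#'   `n_sequences`, `valid`, `sequences` (data.frame), `short_recording`
#' @export
estimate_brs <- function(beats, config = list()) {
  cfg <- utils::modifyList(brs_defaults(), config)
  seqs <- detect_sequences(beats, cfg$min_dsbp_mmhg, cfg$min_dibi_ms,
                           cfg$min_len, cfg$min_r, cfg$lag_beats)
  nseq <- nrow(seqs)
  valid <- nseq >= cfg$min_sequences
  dur <- if (!is.null(beats$beat_times_s) && length(beats$beat_times_s)) {
    diff(range(beats$beat_times_s))
  } else sum(beats$ibi_ms) / 1000
  structure(list(
    brs_ms_per_mmhg = if (valid) mean(seqs$slope_ms_per_mmhg) else NA_real_,
    n_sequences = nseq,
    valid = valid,
    sequences = seqs,
    short_recording = dur < 600),
    class = "brs_estimate")
}

#' @export
print.brs_estimate <- function(x, ...) {
  cat(sprintf("<brs_estimate> %s: %s ms/mmHg over %d sequences%s\n",
              if (x$valid) "valid" else "NOT valid",
              if (x$valid) sprintf("%.2f", x$brs_ms_per_mmhg) else "--",
              x$n_sequences,
              if (x$short_recording) " (short recording)" else ""))
  invisible(x)
}
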