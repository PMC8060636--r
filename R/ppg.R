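# PPG pulse delineation and waveform parametrization: onset, systolic peak,
# dicrotic notch and diastolic peak per pulse; the timing/amplitude panel
# (PI, tS, tC, tD, aS, aD, aDic); the modified augmentation index
# mAI = mean over pulses of (aD - aDic) / (aS - aDic); and the
# last-hour-of-sleep window summary.

# default delineation configuration
ppg_defaults <- function() {
  list(bandpass_hz = c(0.5, 10), refractory_s = 0.3, smooth_ms = 7,
       refine_lowpass_hz = 15, noise_switch_frac = 0.002,
       slope_frac = 0.02, robust_slope_frac = 0.08, prom_frac = 0.05,
       td_mode = "to_diastolic", min_pulses = 100L)
}

# zero-phase band-pass used only to locate beats; amplitudes are read off
# the (lightly smoothed) raw signal
ppg_bandpass <- function(x, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(2, c(band[1] / ny, band[2] / ny), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

ppg_lowpass <- function(x, fs, fc) {
  bf <- signal::butter(4, fc / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Delineate the pulses of a PPG signal
#'
#' Beat locations are found on a zero-phase 0.5-10 Hz band-passed copy;
#' every fiducial is then refined on a lightly smoothed copy of the raw
#' signal so amplitudes stay faithful. Per pulse: the onset is the foot
#' preceding the maximal upslope (walk-back until the slope falls below
#' `slope_frac` of the pulse's maximal upslope); the systolic peak is the
#' local maximum near the detected beat; the diastolic peak is the most
#' prominent interior maximum of the catacrotic segment; the dicrotic notch
#' is the minimum between systolic and diastolic peaks. For notch-less
#' pulses the notch falls back to the maximum of the second derivative on
#' the catacrotic limb and the pulse is flagged non-canonical. Amplitudes
#' are measured above the pulse's own onset value, making them drift-robust.
#'
#' @param ppg a [sampled_signal()] in mV, fs >= 100 Hz, duration >= 5 s
#' @param config optional overrides of `ppg_defaults()`
#' @return data.frame, one row per fully delineated pulse: `onset_s`,
#'   `systolic_peak_s`, `dicrotic_notch_s`, `diastolic_peak_s`,
#'   `next_onset_s`, `baseline_mv`, `aS_mv`, `aDic_mv`, `aD_mv`,
#'   `canonical`, `reason`
#' @export
delineate_pulses <- function(ppg, config = list()) {
  cfg <- utils::modifyList(ppg_defaults(), config)
  check_that(inherits(ppg, "sampled_signal"), "ppg must be a sampled_signal")
  fs <- ppg$fs
  check_that(fs >= 100, "need fs >= 100 Hz")
  check_that(signal_duration(ppg) >= 5, "need at least 5 s of signal")
  x <- ppg$values
  amp_range <- diff(stats::quantile(x, c(0.02, 0.98), names = FALSE))
  if (amp_range < 1e-9) sc_abort("flat signal: no pulses", "sc_quality_error")
  filt <- ppg_bandpass(x, fs, cfg$bandpass_hz)
  # noise-adaptive refinement scale: fiducials are refined on a lightly
  # smoothed copy when the high-frequency noise floor is negligible (keeps
  # sample-exact extrema), and on a zero-phase low-pass otherwise (flat
  # pulse extrema cannot be localized pointwise under broadband noise)
  noise_hat <- stats::mad(x - ppg_lowpass(x, fs, min(40, fs / 2.5)))
  robust <- noise_hat > cfg$noise_switch_frac * amp_range
  sm <- if (robust) ppg_lowpass(x, fs, cfg$refine_lowpass_hz)
        else running_mean(x, round(cfg$smooth_ms * fs / 1000))
  foot_frac <- if (robust) cfg$robust_slope_frac else cfg$slope_frac
  dsm <- c(0, diff(sm)) * fs

  # beats are located on the upstroke of the filtered copy: the systolic
  # rise is much steeper than the diastolic one, so a slope threshold
  # separates them cleanly where an amplitude threshold would not
  dfilt <- c(0, diff(filt)) * fs
  slope_thr <- 0.4 * stats::quantile(dfilt, 0.98, names = FALSE)
  if (slope_thr <= 0) sc_abort("no pulses found", "sc_quality_error")
  up <- local_maxima(dfilt)
  up <- up[dfilt[up] >= slope_thr]
  if (length(up) < 2L) sc_abort("no pulses found", "sc_quality_error")
  min_gap <- round(cfg$refractory_s * fs)
  ord <- up[order(-dfilt[up])]
  kept <- integer(0)
  for (p in ord) if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  up <- sort(kept)

  n <- length(x)
  # systolic peak: hill-climb the smoothed raw signal from each upslope,
  # stopping once the signal has clearly fallen away from the summit
  drop_out <- 0.05 * amp_range
  speaks <- vapply(up, function(u) {
    i <- u; best <- u
    while (i < n) {
      i <- i + 1L
      if (sm[i] > sm[best]) best <- i
      if (sm[best] - sm[i] > drop_out || i - best > min_gap) break
    }
    as.integer(best)
  }, integer(1))
  speaks <- unique(speaks)

  # onset for each beat: foot before the maximal upslope
  onsets <- integer(length(speaks))
  for (k in seq_along(speaks)) {
    lo <- if (k == 1L) 1L else speaks[k - 1L]
    seg <- lo:speaks[k]
    if (length(seg) < 3L) { onsets[k] <- NA_integer_; next }
    u <- seg[which.max(dsm[seg])]
    maxslope <- dsm[u]
    if (!is.finite(maxslope) || maxslope <= 0) { onsets[k] <- NA_integer_; next }
    i <- u
    while (i > lo && dsm[i] > foot_frac * maxslope) i <- i - 1L
    onsets[k] <- i
  }

  rows <- list()
  for (k in seq_len(length(speaks) - 1L)) {
    o <- onsets[k]; s <- speaks[k]; o2 <- onsets[k + 1L]
    if (is.na(o) || is.na(o2) || !(o < s && s < o2)) next
    base <- sm[o]
    aS <- sm[s] - base
    seg_lo <- s + max(2L, round(0.01 * fs))
    seg_hi <- o2 - max(2L, round(0.01 * fs))
    canonical <- TRUE; reason <- ""
    d_idx <- NA_integer_; notch_idx <- NA_integer_
    if (seg_hi - seg_lo >= 5L) {
      seg <- sm[seg_lo:seg_hi]
      lm <- local_maxima(seg)
      if (length(lm)) {
        prom <- peak_prominence(seg, lm)
        best <- lm[which.max(prom)]
        if (max(prom) >= cfg$prom_frac * aS) d_idx <- seg_lo + best - 1L
      }
    }
    if (!is.na(d_idx)) {
      between <- s:d_idx
      notch_idx <- between[which.min(sm[between])]
    } else {
      # notch-less morphology: second-derivative maximum on the catacrotic limb
      lim_hi <- min(o2 - 1L, s + round(0.6 * (o2 - s)))
      if (lim_hi - s > 4L) {
        d2 <- diff(sm[s:lim_hi], differences = 2L)
        notch_idx <- s + which.max(d2)
        d_idx <- notch_idx
      }
      canonical <- FALSE; reason <- "no distinct diastolic wave"
    }
    if (is.na(notch_idx)) { canonical <- FALSE; reason <- "unresolvable catacrotic limb" }
    aDic <- if (!is.na(notch_idx)) sm[notch_idx] - base else NA_real_
    aD <- if (!is.na(d_idx)) sm[d_idx] - base else NA_real_
    if (canonical) {
      ok_order <- o < s && s < notch_idx && notch_idx <= d_idx && d_idx < o2
      ok_amp <- is.finite(aS) && is.finite(aD) && is.finite(aDic) &&
        aS >= aD && aD >= aDic && aDic >= -0.02 * aS
      if (!ok_order) { canonical <- FALSE; reason <- "fiducial order violated" }
      else if (!ok_amp) { canonical <- FALSE; reason <- "amplitude order violated" }
    }
    tt <- function(i) if (is.na(i)) NA_real_ else ppg$t0 + (i - 1) / fs
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = tt(o), systolic_peak_s = tt(s), dicrotic_notch_s = tt(notch_idx),
      diastolic_peak_s = tt(d_idx), next_onset_s = tt(o2),
      baseline_mv = base, aS_mv = aS, aDic_mv = aDic, aD_mv = aD,
      canonical = canonical, reason = reason)
  }
  if (!length(rows)) sc_abort("no pulse could be delineated", "sc_quality_error")
  do.call(rbind, rows)
}

#' Per-pulse waveform parameters from fiducials
#'
#' `PI = next onset - onset`; `tS = systolic peak - onset`;
#' `tC = notch - systolic peak`; `tD = diastolic peak - notch` (or
#' `next onset - notch` when `td_mode = "to_next_onset"`); amplitudes are
#' carried over; `mai_term = (aD - aDic) / (aS - aDic)` (undefined when
#' `aS == aDic`).
#'
#' @param fid one row (or several) of the [delineate_pulses()] table
#' @param td_mode "to_diastolic" (default) or "to_next_onset"
#' @return data.frame: `PI_s`, `tS_s`, `tC_s`, `tD_s`, `aS_mv`, `aD_mv`,
#'   `aDic_mv`, `mai_term`, `canonical`
#' @export
pulse_features <- function(fid, td_mode = c("to_diastolic", "to_next_onset")) {
  td_mode <- match.arg(td_mode)
  denom <- fid$aS_mv - fid$aDic_mv
  mai <- ifelse(is.finite(denom) & abs(denom) > 1e-12,
                (fid$aD_mv - fid$aDic_mv) / denom, NA_real_)
  data.frame(
    PI_s = fid$next_onset_s - fid$onset_s,
    tS_s = fid$systolic_peak_s - fid$onset_s,
    tC_s = fid$dicrotic_notch_s - fid$systolic_peak_s,
    tD_s = if (td_mode == "to_diastolic") fid$diastolic_peak_s - fid$dicrotic_notch_s
           else fid$next_onset_s - fid$dicrotic_notch_s,
    aS_mv = fid$aS_mv, aD_mv = fid$aD_mv, aDic_mv = fid$aDic_mv,
    mai_term = mai,
    canonical = if ("canonical" %in% names(fid)) fid$canonical else TRUE)
}

#' Modified augmentation index
#'
#' Mean over pulses of the per-pulse term `(aD - aDic) / (aS - aDic)`;
#' pulses with an undefined term (aS == aDic) are excluded.
#'
#' @param features data.frame from [pulse_features()], or a numeric vector of
#'   per-pulse terms
#' @return list `mAI` (NA with a `reason` when no term is defined) and
#'   `n_terms`
#' @export
modified_augmentation_index <- function(features) {
  terms <- if (is.data.frame(features)) features$mai_term else as.numeric(features)
  terms <- terms[is.finite(terms)]
  if (!length(terms)) {
    return(list(mAI = NA_real_, n_terms = 0L, reason = "no pulse with a defined term"))
  }
  list(mAI = mean(terms), n_terms = length(terms))
}

#' PPG summary over the last hour of sleep
#'
#' Restricts the signal to `[wake - 3600 s, wake]` (whole window when the
#' sleep period is shorter than an hour, with a flag), delineates it, and
#' averages the waveform panel over canonical pulses; mAI per the modified
#' augmentation index.
#'
#' @param ppg a [sampled_signal()] in mV
#' @param sleep_window list or vector with `onset_s` and `wake_s`
#' @param config optional overrides of `ppg_defaults()`
#' @return a `ppg_window_summary` list: window bounds, `n_pulses`,
#'   `n_noncanonical`, means of `PI_s`, `tS_s`, `tC_s`, `tD_s`, `aS_mv`,
#'   `aD_mv`, `aDic_mv`, `mAI`, and flags `window_short`, `low_quality`
#' @export
last_hour_summary <- function(ppg, sleep_window, config = list()) {
  cfg <- utils::modifyList(ppg_defaults(), config)
  sw <- as.list(sleep_window)
  if (is.null(sw$onset_s)) { sw <- list(onset_s = sleep_window[[1]], wake_s = sleep_window[[2]]) }
  check_that(is.finite(sw$onset_s) && is.finite(sw$wake_s) && sw$wake_s > sw$onset_s,
             "sleep window is empty")
  win_start <- max(sw$onset_s, sw$wake_s - 3600)
  window_short <- (sw$wake_s - sw$onset_s) < 3600
  sub <- signal_window(ppg, win_start, sw$wake_s)
  fid <- delineate_pulses(sub, cfg)
  feats <- pulse_features(fid, td_mode = cfg$td_mode)
  can <- feats[feats$canonical & is.finite(feats$tD_s), , drop = FALSE]
  if (!nrow(can)) sc_abort("no canonical pulse in window", "sc_quality_error")
  mai <- modified_augmentation_index(can)
  structure(list(
    window_start_s = win_start, window_end_s = sw$wake_s,
    n_pulses = nrow(can), n_noncanonical = nrow(feats) - nrow(can),
    PI_s = mean(can$PI_s), tS_s = mean(can$tS_s), tC_s = mean(can$tC_s),
    tD_s = mean(can$tD_s), aS_mv = mean(can$aS_mv), aD_mv = mean(can$aD_mv),
    aDic_mv = mean(can$aDic_mv), mAI = mai$mAI,
    window_short = window_short,
    low_quality = nrow(can) < cfg$min_pulses),
    class = "ppg_window_summary")
}

#' @export
print.ppg_window_summary <- function(x, ...) {
  cat(sprintf(paste0("<ppg_window_summary> [%.0f, %.0f] s, %d pulses (%d excluded)%s%s\n",
                     "  PI %.3f s | tS %.3f  tC %.3f  tD %.3f s\n",
                     "  aS %.3f  aD %.3f  aDic %.3f mV | mAI %.3f\n"),
              x$window_start_s, x$window_end_s, x$n_pulses, x$n_noncanonical,
              if (x$window_short) " [short window]" else "",
              if (x$low_quality) " [low quality]" else "",
              x$PI_s, x$tS_s, x$tC_s, x$tD_s, x$aS_mv, x$aD_mv, x$aDic_mv, x$mAI))
  invisible(x)
}
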