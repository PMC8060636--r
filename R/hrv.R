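# HRV panel per posture segment: mean HR, RMSSD, Welch band powers in the
# LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands of the 4-Hz resampled NN
# tachogram, and the normalized powers nLF / nHF.

# default spectral configuration, overridable per call
hrv_defaults <- function() {
  list(fs_resample = 4, window_samples = 250L, overlap = 0.5,
       band_lf = c(0.04, 0.15), band_hf = c(0.15, 0.40),
       band_total = c(0.003, 0.40), taper = "hann")
}

#' Root mean square of successive differences (RMSSD)
#'
#' `sqrt(mean((nn[i+1] - nn[i])^2))` over the n-1 successive differences of
#' the NN series; the classic vagally-mediated time-domain HRV index.
#'
#' @param nn an [nn_series()], [beat_series()] or numeric vector (ms)
#' @return RMSSD in ms
#' @export
#' @examples
#' rmssd(c(800, 900, 800, 900))  # 100
rmssd <- function(nn) {
  x <- as_nn(nn)$nn_ms
  if (length(x) < 2L) sc_abort("RMSSD needs at least 2 intervals", "sc_validation_error")
  sqrt(mean(diff(x)^2))
}

#' Mean heart rate from NN intervals
#'
#' 60000 divided by the arithmetic mean NN interval (ms).
#'
#' @param nn an [nn_series()], [beat_series()] or numeric vector (ms)
#' @return mean heart rate in bpm
#' @export
mean_hr <- function(nn) {
  x <- as_nn(nn)$nn_ms
  if (length(x) == 0L) sc_abort("empty NN series", "sc_validation_error")
  60000 / mean(x)
}

#' Resample an NN series onto a uniform tachogram
#'
#' Beat times are the cumulative sums of the intervals (s). The interval
#' value is interpolated with a cubic spline onto a uniform grid of rate
#' `fs_hz` spanning `[first beat time, last beat time]`.
#'
#' @param nn an [nn_series()], [beat_series()] or numeric vector (ms)
#' @param fs_hz resampling rate, default 4 Hz
#' @param min_duration_s minimum spanned duration for a meaningful spectrum
#' @return a [sampled_signal()] (ms vs s)
#' @export
resample_nn <- function(nn, fs_hz = 4, min_duration_s = 30) {
  x <- as_nn(nn)$nn_ms
  if (length(x) < 4L) sc_abort("need at least 4 intervals to resample", "sc_validation_error")
  tb <- cumsum(x) / 1000
  if (tb[length(tb)] - tb[1] < min_duration_s) {
    sc_abort(sprintf("series spans %.1f s < %g s minimum", tb[length(tb)] - tb[1], min_duration_s),
             "sc_validation_error")
  }
  grid <- seq(tb[1], tb[length(tb)], by = 1 / fs_hz)
  vals <- stats::spline(tb, x, xout = grid, method = "fmm")$y
  sampled_signal(vals, fs = fs_hz, t0 = grid[1], unit = "ms")
}

# boolean mask of frequencies inside a half-open band [lo, hi)
band_mask <- function(freq, band) {
  freq >= band[1] & freq < band[2]
}

#' Welch averaged-periodogram power spectral density
#'
#' Mean-removed segments of `window_samples` points with fractional
#' `overlap`, Hann (or boxcar) taper with power normalization, one-sided PSD
#' averaged over segments.
#'
#' @param x numeric vector
#' @param fs sampling rate (Hz)
#' @param window_samples segment length in samples
#' @param overlap fractional overlap in [0, 1)
#' @param taper "hann" or "none"
#' @return list with `freq` (Hz) and `psd` (x-unit^2 / Hz)
#' @export
welch_psd <- function(x, fs, window_samples = 250L, overlap = 0.5, taper = "hann") {
  n <- as.integer(window_samples)
  check_that(length(x) >= n, "signal shorter than one window")
  check_that(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  w <- switch(taper,
              hann = 0.5 * (1 - cos(2 * pi * seq_len(n) / n)),
              none = rep(1, n),
              sc_abort("unknown taper", "sc_validation_error"))
  step <- max(1L, as.integer(round(n * (1 - overlap))))
  starts <- seq(1L, length(x) - n + 1L, by = step)
  scale <- fs * sum(w^2)
  nh <- n %/% 2L
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / scale
    one <- p[seq_len(nh + 1L)]
    one[2:nh] <- 2 * one[2:nh]          # fold negative frequencies
    if (n %% 2L == 1L) one[nh + 1L] <- 2 * one[nh + 1L]
    acc <- acc + one
  }
  list(freq = (0:nh) * fs / n, psd = acc / length(starts))
}

#' Band powers of an NN tachogram
#'
#' Welch PSD of the tachogram (see [welch_psd()]); band powers are the PSD
#' integrals over half-open bands: LF `[0.04, 0.15)` Hz, HF `[0.15, 0.40)`
#' Hz, and total power over `[0.003, 0.40)` Hz (the lower edge excludes
#' DC/ultra-low-frequency leakage). `nLF = pLF / (pLF + pHF)` and
#' `nHF = 1 - nLF`, the normalized-unit convention under which the two rows
#' sum to one.
#'
#' @param tachogram a [sampled_signal()] from [resample_nn()]
#' @param config optional overrides of `hrv_defaults()`
#' @return list `pLF_ms2`, `pHF_ms2`, `totalPower_ms2`, `nLF`, `nHF`
#' @export
band_powers <- function(tachogram, config = list()) {
  cfg <- utils::modifyList(hrv_defaults(), config)
  x <- tachogram$values
  if (length(x) < cfg$window_samples) {
    sc_abort(sprintf("tachogram has %d samples < %d (one %d-sample window = %.1f s at %g Hz)",
                     length(x), cfg$window_samples, cfg$window_samples,
                     cfg$window_samples / cfg$fs_resample, cfg$fs_resample),
             "sc_validation_error")
  }
  ps <- welch_psd(x, fs = tachogram$fs, window_samples = cfg$window_samples,
                  overlap = cfg$overlap, taper = cfg$taper)
  df <- ps$freq[2] - ps$freq[1]
  p_band <- function(band) sum(ps$psd[band_mask(ps$freq, band)]) * df
  pLF <- p_band(cfg$band_lf)
  pHF <- p_band(cfg$band_hf)
  tot <- p_band(cfg$band_total)
  denom <- pLF + pHF
  nLF <- if (denom > 0) pLF / denom else NA_real_
  list(pLF_ms2 = pLF, pHF_ms2 = pHF, totalPower_ms2 = tot,
       nLF = nLF, nHF = if (is.na(nLF)) NA_real_ else 1 - nLF)
}

#' Full HRV panel for one posture segment
#'
#' @param nn an [nn_series()] (or coercible)
#' @param posture "supine" or "standing"
#' @param config optional spectral overrides (see [band_powers()])
#' @return an `hrv_summary` list: `meanHR_bpm`, `RMSSD_ms`, `pLF_ms2`,
#'   `pHF_ms2`, `totalPower_ms2`, `nLF`, `nHF`, `posture`,
#'   `segment_duration_s`
#' @export
hrv_summary <- function(nn, posture = "supine", config = list()) {
  nn <- as_nn(nn)
  cfg <- utils::modifyList(hrv_defaults(), config)
  tach <- resample_nn(nn, fs_hz = cfg$fs_resample)
  bp <- band_powers(tach, cfg)
  structure(c(list(meanHR_bpm = mean_hr(nn), RMSSD_ms = rmssd(nn)), bp,
              list(posture = posture,
                   segment_duration_s = sum(nn$nn_ms) / 1000)),
            class = "hrv_summary")
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf(paste0("<hrv_summary> %s, %.0f s\n",
                     "  HR %.1f bpm | RMSSD %.1f ms\n",
                     "  pLF %.1f  pHF %.1f  total %.1f ms^2 | nLF %.2f  nHF %.2f\n"),
              x$posture, x$segment_duration_s, x$meanHR_bpm, x$RMSSD_ms,
              x$pLF_ms2, x$pHF_ms2, x$totalPower_ms2, x$nLF, x$nHF))
  invisible(x)
}

#' Assemble an orthostatic test from two posture segments
#'
#' @param supine,standing [nn_series()] for each posture
#' @param protocol "3-3" (3 min per posture) or "6-6"
#' @return an `orthostatic_test` list
#' @export
orthostatic_test <- function(supine, standing, protocol = c("3-3", "6-6")) {
  protocol <- match.arg(protocol)
  supine <- as_nn(supine); standing <- as_nn(standing)
  check_that(length(supine$nn_ms) > 0 && length(standing$nn_ms) > 0,
             "both segments must be non-empty")
  structure(list(supine = supine, standing = standing, protocol = protocol,
                 nominal_segment_s = if (protocol == "3-3") 180 else 360),
            class = "orthostatic_test")
}

#' HRV panel for both postures of an orthostatic test
#'
#' Computes the full panel independently for the supine and standing
#' segments. A segment that fails its quality checks yields a missing-value
#' summary carrying the failure reason instead of an error.
#'
#' @param test an [orthostatic_test()]
#' @param config optional spectral overrides
#' @return named list `supine`, `standing` of `hrv_summary` (or missing-value
#'   summaries with a `failure_reason` field)
#' @export
analyze_orthostatic <- function(test, config = list()) {
  check_that(inherits(test, "orthostatic_test"), "test must be an orthostatic_test")
  one <- function(nn, posture) {
    tryCatch(hrv_summary(nn, posture, config),
             sc_error = function(e) {
               structure(list(meanHR_bpm = NA_real_, RMSSD_ms = NA_real_,
                              pLF_ms2 = NA_real_, pHF_ms2 = NA_real_,
                              totalPower_ms2 = NA_real_, nLF = NA_real_,
                              nHF = NA_real_, posture = posture,
                              segment_duration_s = sum(nn$nn_ms) / 1000,
                              failure_reason = conditionMessage(e)),
                         class = "hrv_summary")
             })
  }
  list(supine = one(test$supine, "supine"),
       standing = one(test$standing, "standing"))
}

#' Flatten HRV summaries into a result table row set
#'
#' @param ... `hrv_summary` objects (named or not)
#' @return data.frame with columns `posture`, `meanHR_bpm`, `RMSSD_ms`,
#'   `pLF_ms2`, `pHF_ms2`, `totalPower_ms2`, `nLF`, `nHF`,
#'   `segment_duration_s`
#' @export
hrv_table <- function(...) {
  rows <- list(...)
  if (length(rows) == 1L && !inherits(rows[[1]], "hrv_summary")) rows <- rows[[1]]
  do.call(rbind, lapply(rows, function(s) {
    data.frame(posture = s$posture, meanHR_bpm = s$meanHR_bpm,
               RMSSD_ms = s$RMSSD_ms, pLF_ms2 = s$pLF_ms2, pHF_ms2 = s$pHF_ms2,
               totalPower_ms2 = s$totalPower_ms2, nLF = s$nLF, nHF = s$nHF,
               segment_duration_s = s$segment_duration_s)
  }))
}
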