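# Synthetic-signal generators with analytic ground truth. Each generator
# emulates one input class of the pipeline: oscillatory NN series for HRV,
# SBP-IBI pairs with a known baroreflex gain, PPG pulse trains with known
# fiducials, and triaxial wrist accelerometry with a known still (sleep)
# window. All take an explicit integer seed and restore the caller's RNG
# state on exit.

#' Specification for a simulated RR/NN interval series
#'
#' The simulated NN interval at cumulative beat time `t` is
#' `mean_nn_ms + lf_amp_ms * sin(2*pi*lf_freq_hz*t) +
#'  hf_amp_ms * sin(2*pi*hf_freq_hz*t) + N(0, noise_sd_ms)`.
#' A pure sinusoidal modulation of amplitude A contributes band power A^2/2
#' (ms^2), which the truth record carries.
#'
#' @param mean_nn_ms mean NN interval (ms)
#' @param lf_amp_ms,lf_freq_hz low-frequency modulation amplitude (ms) and
#'   frequency (Hz, in [0.04, 0.15))
#' @param hf_amp_ms,hf_freq_hz high-frequency modulation amplitude (ms) and
#'   frequency (Hz, in [0.15, 0.40))
#' @param noise_sd_ms white-noise SD added per beat (ms)
#' @param duration_s record duration (s)
#' @param ectopic_rate fraction of beats replaced by premature short-long
#'   pairs, in [0, 0.2)
#' @param seed integer seed
#' @export
rr_sim_spec <- function(mean_nn_ms = 900, lf_amp_ms = 30, lf_freq_hz = 0.10,
                        hf_amp_ms = 20, hf_freq_hz = 0.25, noise_sd_ms = 0,
                        duration_s = 300, ectopic_rate = 0, seed = 1) {
  check_that(mean_nn_ms > 0, "mean_nn_ms must be positive")
  check_that(lf_freq_hz >= 0.04 && lf_freq_hz < 0.15, "lf_freq_hz must lie in [0.04, 0.15)")
  check_that(hf_freq_hz >= 0.15 && hf_freq_hz < 0.40, "hf_freq_hz must lie in [0.15, 0.40)")
  check_that(ectopic_rate >= 0 && ectopic_rate < 0.2, "ectopic_rate must lie in [0, 0.2)")
  check_that(lf_amp_ms >= 0 && hf_amp_ms >= 0 && noise_sd_ms >= 0, "amplitudes must be >= 0")
  check_that(duration_s > 0, "duration_s must be positive")
  structure(as.list(environment()), class = "rr_sim_spec")
}

#' Simulate an RR interval series with known band powers
#'
#' Generates beat-by-beat NN intervals per [rr_sim_spec()]. If
#' `ectopic_rate > 0`, randomly chosen beats are displaced as premature
#' beats: the two intervals around the chosen beat (jointly `S`) become a
#' short-long pair `0.3*S, 0.7*S`, preserving both total time and series
#' length — the classic premature-beat-with-compensatory-pause pattern.
#'
#' @param spec an [rr_sim_spec()]
#' @return list with `beats` (a [beat_series()], all flags "normal" — the
#'   contamination is for the cleaning stage to find), and `truth`: analytic
#'   band powers `pLF_ms2 = lf_amp^2/2`, `pHF_ms2 = hf_amp^2/2`, the
#'   pre-contamination series `clean_nn_ms`, and `ectopic_beats` (indices of
#'   the displaced intervals).
#' @export
simulate_rr <- function(spec) {
  check_that(inherits(spec, "rr_sim_spec"), "spec must be an rr_sim_spec")
  with_seed(spec$seed, {
    nn <- numeric(0)
    t <- 0
    # beat-time recursion: each interval is evaluated at the time of the
    # beat that opens it
    while (t < spec$duration_s) {
      v <- spec$mean_nn_ms +
        spec$lf_amp_ms * sin(2 * pi * spec$lf_freq_hz * t) +
        spec$hf_amp_ms * sin(2 * pi * spec$hf_freq_hz * t) +
        if (spec$noise_sd_ms > 0) stats::rnorm(1, 0, spec$noise_sd_ms) else 0
      v <- max(v, 0.2 * spec$mean_nn_ms)
      nn <- c(nn, v)
      t <- t + v / 1000
    }
    clean <- nn
    ect_idx <- integer(0)
    if (spec$ectopic_rate > 0 && length(nn) >= 4) {
      n_ect <- max(1L, round(spec$ectopic_rate * length(nn)))
      cand <- sample(seq(2L, length(nn) - 1L))
      for (i in cand) {
        if (length(ect_idx) >= n_ect) break
        if (any(abs(ect_idx - i) < 3L)) next  # keep pairs disjoint
        ect_idx <- c(ect_idx, i)
      }
      ect_idx <- sort(ect_idx)
      for (i in ect_idx) {
        s <- nn[i] + nn[i + 1L]
        nn[i] <- 0.3 * s
        nn[i + 1L] <- 0.7 * s
      }
    }
    list(
      beats = beat_series(nn, label = "unspecified"),
      truth = list(pLF_ms2 = spec$lf_amp_ms^2 / 2,
                   pHF_ms2 = spec$hf_amp_ms^2 / 2,
                   totalPower_ms2 = spec$lf_amp_ms^2 / 2 + spec$hf_amp_ms^2 / 2,
                   clean_nn_ms = clean,
                   ectopic_beats = ect_idx)
    )
  })
}

#' Specification for a simulated SBP-IBI recording
#'
#' Blood pressure alternates flat holds with monotone ramps; the inter-beat
#' interval follows the pressure linearly with gain `gain_ms_per_mmhg` plus
#' Gaussian noise, emulating spontaneous baroreflex sequences.
#'
#' Default ramp geometry (step 4 mmHg/beat over 8 beats) is chosen so the
#' per-beat IBI change at the smallest gain of interest clears the 5-ms
#' sequence-validation floor by about two SD of the beat-to-beat noise; see
#' the methods vignette.
#'
#' @param gain_ms_per_mmhg true baroreflex gain (ms/mmHg), >= 0
#' @param n_beats total number of beats
#' @param sbp_base_mmhg baseline systolic pressure (mmHg)
#' @param ramp_length_beats beats per imposed ramp (>= 3)
#' @param ramp_step_mmhg per-beat SBP increment on ramps (>= 1 mmHg)
#' @param noise_sd_ms IBI noise SD (ms)
#' @param ibi_base_ms IBI at baseline pressure (ms)
#' @param hold_beats flat beats between ramps
#' @param seed integer seed
#' @export
baro_sim_spec <- function(gain_ms_per_mmhg = 15, n_beats = 300,
                          sbp_base_mmhg = 120, ramp_length_beats = 8,
                          ramp_step_mmhg = 4, noise_sd_ms = 0,
                          ibi_base_ms = 1000, hold_beats = 4, seed = 1) {
  check_that(gain_ms_per_mmhg >= 0, "gain must be >= 0")
  check_that(ramp_length_beats >= 3, "ramp_length_beats must be >= 3")
  check_that(ramp_step_mmhg >= 1, "ramp_step_mmhg must be >= 1 mmHg")
  check_that(hold_beats >= 1, "hold_beats must be >= 1")
  check_that(noise_sd_ms >= 0 && ibi_base_ms > 0 && sbp_base_mmhg > 0, "invalid spec")
  if (n_beats < hold_beats + ramp_length_beats) {
    sc_abort("n_beats too small to embed one ramp", "sc_validation_error")
  }
  structure(as.list(environment()), class = "baro_sim_spec")
}

#' Number of beats needed for a given number of ramps
#' @param n_ramps ramps wanted
#' @param ramp_length_beats,hold_beats ramp geometry (see [baro_sim_spec()])
#' @export
baro_beats_for_ramps <- function(n_ramps, ramp_length_beats = 8, hold_beats = 4) {
  n_ramps * (ramp_length_beats + hold_beats) + hold_beats
}

#' Simulate a beat-wise SBP-IBI recording with known baroreflex gain
#'
#' SBP starts at a flat hold, then alternates up and down ramps (per-beat
#' step `ramp_step_mmhg`, length `ramp_length_beats`) separated by flat
#' holds, so pressure excursions return to baseline.
#' `IBI_n = ibi_base_ms + gain * (SBP_n - sbp_base_mmhg) + N(0, noise_sd_ms)`.
#'
#' @param spec a [baro_sim_spec()]
#' @return list with `beats` (fields `sbp_mmhg`, `ibi_ms`, `beat_times_s`,
#'   class `beat_pressure_series`) and `truth` (`gain_ms_per_mmhg`,
#'   `n_ramps`, and a `ramps` data.frame of start/end beat and direction).
#' @export
simulate_baro <- function(spec) {
  check_that(inherits(spec, "baro_sim_spec"), "spec must be a baro_sim_spec")
  L <- spec$ramp_length_beats; H <- spec$hold_beats
  sbp <- rep(spec$sbp_base_mmhg, H)
  ramps <- list()
  level <- spec$sbp_base_mmhg
  dir_up <- TRUE
  while (length(sbp) + L <= spec$n_beats) {
    step <- if (dir_up) spec$ramp_step_mmhg else -spec$ramp_step_mmhg
    ramp <- level + step * seq_len(L)
    ramps[[length(ramps) + 1L]] <- data.frame(
      start_beat = length(sbp),          # hold beat preceding the ramp joins the run
      end_beat = length(sbp) + L,
      direction = if (dir_up) "up" else "down")
    sbp <- c(sbp, ramp)
    level <- ramp[L]
    dir_up <- !dir_up
    sbp <- c(sbp, rep(level, min(H, spec$n_beats - length(sbp))))
  }
  if (length(sbp) < spec$n_beats) sbp <- c(sbp, rep(level, spec$n_beats - length(sbp)))
  ibi <- with_seed(spec$seed, {
    spec$ibi_base_ms + spec$gain_ms_per_mmhg * (sbp - spec$sbp_base_mmhg) +
      if (spec$noise_sd_ms > 0) stats::rnorm(length(sbp), 0, spec$noise_sd_ms) else 0
  })
  beats <- structure(list(sbp_mmhg = sbp, ibi_ms = ibi,
                          beat_times_s = cumsum(ibi) / 1000),
                     class = "beat_pressure_series")
  list(beats = beats,
       truth = list(gain_ms_per_mmhg = spec$gain_ms_per_mmhg,
                    n_ramps = length(ramps),
                    ramps = do.call(rbind, ramps)))
}

#' Specification for a simulated PPG pulse train
#'
#' Each pulse is a piecewise raised-cosine template: rise from onset
#' (baseline) to the systolic peak `aS` at `tS`; catacrotic descent to the
#' dicrotic notch `aDic` at `tS + tC`; secondary rise to the diastolic peak
#' `aD` at `tS + tC + tD`; decay back to baseline before the next onset.
#' Raised-cosine segments are smooth with zero slope at their ends, so the
#' template's local extrema sit exactly at the specified fiducials.
#'
#' @param fs sampling rate (Hz)
#' @param n_pulses number of pulses
#' @param pi_s pulse interval (s)
#' @param tS_s,tC_s,tD_s systolic, catacrotic, diastolic segment durations
#'   (s), with `tS_s + tC_s + tD_s <= pi_s`
#' @param aS_mv,aD_mv,aDic_mv systolic, diastolic, dicrotic-notch amplitudes
#'   above baseline (mV), `0 <= aDic <= aD <= aS`
#' @param baseline_mv baseline level (mV)
#' @param noise_sd_mv additive white-noise SD (mV)
#' @param seed integer seed
#' @export
ppg_sim_spec <- function(fs = 1000, n_pulses = 30, pi_s = 1.0,
                         tS_s = 0.15, tC_s = 0.20, tD_s = 0.15,
                         aS_mv = 2.0, aD_mv = 1.5, aDic_mv = 1.0,
                         baseline_mv = 0, noise_sd_mv = 0, seed = 1) {
  check_that(fs > 0 && n_pulses >= 1 && pi_s > 0, "invalid spec")
  check_that(tS_s > 0 && tC_s > 0 && tD_s > 0, "segment durations must be positive")
  check_that(tS_s + tC_s + tD_s <= pi_s, "tS + tC + tD must not exceed the pulse interval")
  check_that(aDic_mv >= 0 && aDic_mv <= aD_mv && aD_mv <= aS_mv,
             "canonical morphology requires 0 <= aDic <= aD <= aS")
  check_that(noise_sd_mv >= 0, "noise_sd_mv must be >= 0")
  structure(as.list(environment()), class = "ppg_sim_spec")
}

# raised-cosine ramp between two values; zero slope at both ends
raised_cosine <- function(v_from, v_to, tau, d) {
  v_from + (v_to - v_from) * (1 - cos(pi * pmin(pmax(tau / d, 0), 1))) / 2
}

#' Simulate a PPG pulse train with known fiducials
#'
#' @param spec a [ppg_sim_spec()]
#' @return list with `signal` (a [sampled_signal()], unit mV) and `truth`, a
#'   data.frame of per-pulse fiducial times and amplitudes (`onset_s`,
#'   `systolic_s`, `notch_s`, `diastolic_s`, `next_onset_s`, `aS_mv`,
#'   `aD_mv`, `aDic_mv`).
#' @export
simulate_ppg <- function(spec) {
  check_that(inherits(spec, "ppg_sim_spec"), "spec must be a ppg_sim_spec")
  dt <- 1 / spec$fs
  t <- seq(0, spec$n_pulses * spec$pi_s - dt, by = dt)
  tau <- t %% spec$pi_s
  tS <- spec$tS_s; tC <- spec$tC_s; tD <- spec$tD_s
  rest <- spec$pi_s - (tS + tC + tD)
  v <- numeric(length(t))
  seg1 <- tau < tS
  v[seg1] <- raised_cosine(0, spec$aS_mv, tau[seg1], tS)
  seg2 <- tau >= tS & tau < tS + tC
  v[seg2] <- raised_cosine(spec$aS_mv, spec$aDic_mv, tau[seg2] - tS, tC)
  seg3 <- tau >= tS + tC & tau < tS + tC + tD
  v[seg3] <- raised_cosine(spec$aDic_mv, spec$aD_mv, tau[seg3] - tS - tC, tD)
  seg4 <- tau >= tS + tC + tD
  if (rest > 0) {
    v[seg4] <- raised_cosine(spec$aD_mv, 0, tau[seg4] - tS - tC - tD, rest)
  } else {
    v[seg4] <- 0
  }
  v <- v + spec$baseline_mv
  if (spec$noise_sd_mv > 0) {
    v <- v + with_seed(spec$seed, stats::rnorm(length(v), 0, spec$noise_sd_mv))
  }
  onsets <- (seq_len(spec$n_pulses) - 1) * spec$pi_s
  truth <- data.frame(
    onset_s = onsets,
    systolic_s = onsets + tS,
    notch_s = onsets + tS + tC,
    diastolic_s = onsets + tS + tC + tD,
    next_onset_s = onsets + spec$pi_s,
    aS_mv = spec$aS_mv, aD_mv = spec$aD_mv, aDic_mv = spec$aDic_mv)
  list(signal = sampled_signal(v, spec$fs, t0 = 0, unit = "mV"), truth = truth)
}

#' Specification for simulated wrist actigraphy
#'
#' Outside the sleep window the arm performs large random orientation
#' excursions plus motion noise; inside, the signal is gravity-dominated at a
#' near-constant arm angle with small jitter.
#'
#' @param fs sampling rate (Hz)
#' @param total_duration_s record duration (s)
#' @param sleep_onset_s,wake_s still (sleep) window bounds,
#'   `0 <= sleep_onset_s < wake_s <= total_duration_s`; pass
#'   `sleep_onset_s = wake_s = NA` for an all-active trace
#' @param active_motion_sd_g motion noise SD while awake (g)
#' @param still_motion_sd_g jitter SD while asleep (g)
#' @param seed integer seed
#' @export
acti_sim_spec <- function(fs = 25, total_duration_s = 28800,
                          sleep_onset_s = 1800, wake_s = 27000,
                          active_motion_sd_g = 0.10, still_motion_sd_g = 0.005,
                          seed = 1) {
  check_that(fs > 0 && total_duration_s > 0, "invalid spec")
  if (!is.na(sleep_onset_s) || !is.na(wake_s)) {
    check_that(!is.na(sleep_onset_s) && !is.na(wake_s), "give both bounds or neither")
    check_that(sleep_onset_s >= 0 && sleep_onset_s < wake_s &&
               wake_s <= total_duration_s,
               "need 0 <= sleep_onset_s < wake_s <= total_duration_s")
  }
  check_that(active_motion_sd_g >= 0 && still_motion_sd_g >= 0, "noise SDs must be >= 0")
  structure(as.list(environment()), class = "acti_sim_spec")
}

#' Simulate triaxial wrist accelerometry with a known still window
#'
#' @param spec an [acti_sim_spec()]
#' @return list with `acc` (named list of three [sampled_signal()]: x, y, z,
#'   unit g) and `truth` (`sleep_onset_s`, `wake_s`; both `NA` for an
#'   all-active trace).
#' @export
simulate_actigraphy <- function(spec) {
  check_that(inherits(spec, "acti_sim_spec"), "spec must be an acti_sim_spec")
  n <- round(spec$total_duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  asleep <- if (is.na(spec$sleep_onset_s)) rep(FALSE, n)
            else t >= spec$sleep_onset_s & t < spec$wake_s
  with_seed(spec$seed, {
    # active: hold a random orientation for ~6 s at a time so successive
    # 5-s epochs almost always see a large arm-angle change
    seg_len <- round(6 * spec$fs)
    n_seg <- ceiling(n / seg_len)
    dirs <- matrix(stats::rnorm(3 * n_seg), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    seg_of <- pmin(((seq_len(n) - 1) %/% seg_len) + 1L, n_seg)
    g <- dirs[seg_of, , drop = FALSE]
    # asleep: fixed orientation, gravity mostly along z
    g_still <- c(0.15, 0.25, 0.96); g_still <- g_still / sqrt(sum(g_still^2))
    g[asleep, 1] <- g_still[1]; g[asleep, 2] <- g_still[2]; g[asleep, 3] <- g_still[3]
    sd_vec <- ifelse(asleep, spec$still_motion_sd_g, spec$active_motion_sd_g)
    acc <- g + matrix(stats::rnorm(3 * n), ncol = 3) * sd_vec
    out <- list(x = sampled_signal(acc[, 1], spec$fs, unit = "g"),
                y = sampled_signal(acc[, 2], spec$fs, unit = "g"),
                z = sampled_signal(acc[, 3], spec$fs, unit = "g"))
    list(acc = out,
         truth = list(sleep_onset_s = spec$sleep_onset_s, wake_s = spec$wake_s))
  })
}
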