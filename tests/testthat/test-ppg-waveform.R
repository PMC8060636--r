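# Pulse delineation against the generator truth, waveform features, the
# modified augmentation index, and the last-hour summary.

truth_errors_samples <- function(fid, truth, fs) {
  tr <- truth[seq_len(nrow(fid)), ]
  cbind(onset = fid$onset_s - tr$onset_s,
        systolic = fid$systolic_peak_s - tr$systolic_s,
        notch = fid$dicrotic_notch_s - tr$notch_s,
        diastolic = fid$diastolic_peak_s - tr$diastolic_s) * fs
}

test_that("noise-free delineation recovers every fiducial and amplitude", {
  sim <- simulate_ppg(ppg_sim_spec(n_pulses = 12))
  fid <- delineate_pulses(sim$signal)
  can <- fid$canonical
  expect_gte(sum(can), 10)
  err <- truth_errors_samples(fid, sim$truth, 1000)[can, ]
  expect_lte(max(abs(err)), 2)
  tr <- sim$truth[seq_len(nrow(fid)), ]
  expect_lte(max(abs(fid$aS_mv[can] / tr$aS_mv[can] - 1)), 0.02)
  expect_lte(max(abs(fid$aD_mv[can] / tr$aD_mv[can] - 1)), 0.02)
  expect_lte(max(abs(fid$aDic_mv[can] / tr$aDic_mv[can] - 1)), 0.02)
  # two identical pulses 1 s apart
  expect_equal(fid$next_onset_s[can] - fid$onset_s[can],
               rep(1.0, sum(can)), tolerance = 3e-3)
})

test_that("delineation under 1% noise stays within the curvature-limited bounds", {
  sim <- simulate_ppg(ppg_sim_spec(n_pulses = 12, noise_sd_mv = 0.02, seed = 3))
  truth <- simulate_ppg(ppg_sim_spec(n_pulses = 12))$truth
  fid <- delineate_pulses(sim$signal)
  can <- fid$canonical
  expect_gte(sum(can), 10)
  err <- abs(truth_errors_samples(fid, truth, 1000)[can, ])
  expect_lte(max(err[, "onset"]), 5)
  expect_lte(max(err[, "notch"]), 5)
  expect_lte(max(err[, "systolic"]), 8)   # flat systolic summit: bias-limited
  expect_lte(max(err[, "diastolic"]), 15) # flat diastolic runoff: curvature-limited
})

test_that("scale and offset changes move amplitudes but not timings or mAI", {
  sim <- simulate_ppg(ppg_sim_spec(n_pulses = 8))
  fid <- delineate_pulses(sim$signal)
  scaled <- sim$signal
  scaled$values <- 3 * scaled$values + 10
  fid2 <- delineate_pulses(scaled)
  expect_equal(nrow(fid2), nrow(fid))
  expect_lte(max(abs(fid2$onset_s - fid$onset_s)), 2e-3)
  expect_lte(max(abs(fid2$systolic_peak_s - fid$systolic_peak_s)), 2e-3)
  expect_equal(fid2$aS_mv, 3 * fid$aS_mv, tolerance = 1e-6)
  expect_equal(fid2$aDic_mv, 3 * fid$aDic_mv, tolerance = 1e-6)
  m1 <- modified_augmentation_index(pulse_features(fid[fid$canonical, ]))
  m2 <- modified_augmentation_index(pulse_features(fid2[fid2$canonical, ]))
  expect_equal(m2$mAI, m1$mAI, tolerance = 1e-6)
})

test_that("pulse features are plain differences and ratios of the fiducials", {
  fid <- data.frame(onset_s = 0, systolic_peak_s = 0.15, dicrotic_notch_s = 0.35,
                    diastolic_peak_s = 0.50, next_onset_s = 1.0,
                    baseline_mv = 0, aS_mv = 2.0, aDic_mv = 1.0, aD_mv = 1.5,
                    canonical = TRUE)
  f <- pulse_features(fid)
  expect_equal(f$tS_s, 0.15)
  expect_equal(f$tC_s, 0.20)
  expect_equal(f$tD_s, 0.15)
  expect_equal(f$PI_s, 1.0)
  expect_equal(f$mai_term, 0.5)
  expect_lte(f$tS_s + f$tC_s + f$tD_s, f$PI_s)

  # limits of the augmentation term
  lim <- fid
  lim$aD_mv <- lim$aDic_mv
  expect_equal(pulse_features(lim)$mai_term, 0)
  lim$aD_mv <- lim$aS_mv
  expect_equal(pulse_features(lim)$mai_term, 1)
  # aS == aDic leaves the term undefined
  degen <- fid; degen$aDic_mv <- degen$aS_mv; degen$aD_mv <- degen$aS_mv
  expect_true(is.na(pulse_features(degen)$mai_term))

  # the alternative diastolic-time convention runs to the next onset
  expect_equal(pulse_features(fid, td_mode = "to_next_onset")$tD_s, 0.65)
})

test_that("the modified augmentation index is the mean of defined terms", {
  expect_equal(modified_augmentation_index(c(0.5, 0.5, 0.5))$mAI, 0.5)
  expect_equal(modified_augmentation_index(c(0, 1))$mAI, 0.5)
  none <- modified_augmentation_index(c(NA_real_, NA_real_))
  expect_true(is.na(none$mAI))
  expect_match(none$reason, "no pulse")
  sim <- simulate_ppg(ppg_sim_spec(n_pulses = 10))
  fid <- delineate_pulses(sim$signal)
  m <- modified_augmentation_index(pulse_features(fid[fid$canonical, ]))
  expect_gte(m$mAI, 0); expect_lte(m$mAI, 1)
})

test_that("the last-hour summary reflects only the final hour of sleep", {
  # compact surrogate night at 100 Hz: 30 min of one morphology followed by
  # a distinct final segment; a shortened "hour" keeps the test fast
  fs <- 100
  early <- simulate_ppg(ppg_sim_spec(fs = fs, n_pulses = 600, aS_mv = 2.0,
                                     aD_mv = 1.5, aDic_mv = 1.0))
  late <- simulate_ppg(ppg_sim_spec(fs = fs, n_pulses = 600, aS_mv = 1.6,
                                    aD_mv = 1.1, aDic_mv = 0.9))
  night <- sampled_signal(c(early$signal$values, late$signal$values), fs, unit = "mV")
  sw <- list(onset_s = 0, wake_s = 1200)
  sub <- signal_window(night, sw$wake_s - 3600, sw$wake_s)
  expect_equal(length(sub$values), length(night$values))

  sum_late <- last_hour_summary(night, list(onset_s = 900, wake_s = 1200))
  # window [wake-3600, wake] clamped to onset: spans 300 s of the late segment
  expect_true(sum_late$window_short)
  expect_equal(sum_late$aS_mv, 1.6, tolerance = 0.02)
  expect_equal(sum_late$mAI, (1.1 - 0.9) / (1.6 - 0.9), tolerance = 0.02)
  expect_equal(sum_late$PI_s, 1.0, tolerance = 0.01)
})

test_that("a uniform train summarizes to its single-pulse features", {
  sim <- simulate_ppg(ppg_sim_spec(fs = 200, n_pulses = 130))
  s <- last_hour_summary(sim$signal, list(onset_s = 0, wake_s = 130),
                         config = list(min_pulses = 100L))
  expect_true(s$window_short)
  expect_false(s$low_quality)
  expect_equal(s$tS_s, 0.15, tolerance = 0.02)
  expect_equal(s$tC_s, 0.20, tolerance = 0.02)
  expect_equal(s$tD_s, 0.15, tolerance = 0.02)
  expect_equal(s$mAI, 0.5, tolerance = 0.01)
  expect_error(last_hour_summary(sim$signal, list(onset_s = 100, wake_s = 100)),
               class = "sc_validation_error")
})

test_that("canonical pulses close in time and order amplitudes", {
  sim <- simulate_ppg(ppg_sim_spec(n_pulses = 10, noise_sd_mv = 0.01, seed = 5))
  fid <- delineate_pulses(sim$signal)
  f <- pulse_features(fid[fid$canonical, ])
  expect_true(all(f$tS_s + f$tC_s + f$tD_s <= f$PI_s + 1e-9))
  expect_true(all(f$aS_mv >= f$aD_mv & f$aD_mv >= f$aDic_mv))
})

test_that("flat signals are a quality error", {
  expect_error(delineate_pulses(sampled_signal(rep(1, 8000), 1000)),
               class = "sc_quality_error")
})
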