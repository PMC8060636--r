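# Generators: analytic truths, seeding contracts, construction geometry.

test_that("simulated RR series carries analytic band powers and obeys seeding", {
  sim <- simulate_rr(rr_sim_spec(lf_amp_ms = 30, hf_amp_ms = 20, seed = 5))
  expect_equal(sim$truth$pLF_ms2, 450)
  expect_equal(sim$truth$pHF_ms2, 200)

  flat <- simulate_rr(rr_sim_spec(lf_amp_ms = 0, hf_amp_ms = 0, duration_s = 60))
  expect_equal(sim$truth$pLF_ms2 + sim$truth$pHF_ms2, sim$truth$totalPower_ms2)
  expect_true(all(flat$beats$intervals_ms == flat$beats$intervals_ms[1]))

  a <- simulate_rr(rr_sim_spec(noise_sd_ms = 5, duration_s = 60, seed = 11))
  b <- simulate_rr(rr_sim_spec(noise_sd_ms = 5, duration_s = 60, seed = 11))
  c <- simulate_rr(rr_sim_spec(noise_sd_ms = 5, duration_s = 60, seed = 12))
  expect_identical(a$beats$intervals_ms, b$beats$intervals_ms)
  expect_false(identical(a$beats$intervals_ms, c$beats$intervals_ms))
})

test_that("noise-free RR variance matches the analytic A^2/2 sum within 1%", {
  sim <- simulate_rr(rr_sim_spec(lf_amp_ms = 30, hf_amp_ms = 20, duration_s = 600))
  v <- stats::var(sim$beats$intervals_ms)
  expect_equal(v, 450 + 200, tolerance = 0.01)
})

test_that("ectopic injection preserves total time and is a short-long pair", {
  sim <- simulate_rr(rr_sim_spec(ectopic_rate = 0.02, duration_s = 300, seed = 3))
  expect_gt(length(sim$truth$ectopic_beats), 0)
  expect_equal(sum(sim$beats$intervals_ms), sum(sim$truth$clean_nn_ms))
  expect_equal(length(sim$beats$intervals_ms), length(sim$truth$clean_nn_ms))
  i <- sim$truth$ectopic_beats[1]
  s <- sim$truth$clean_nn_ms[i] + sim$truth$clean_nn_ms[i + 1]
  expect_equal(sim$beats$intervals_ms[i], 0.3 * s)
  expect_equal(sim$beats$intervals_ms[i + 1], 0.7 * s)
})

test_that("simulated pressure ramps are collinear at the true gain", {
  spec <- baro_sim_spec(gain_ms_per_mmhg = 15, n_beats = baro_beats_for_ramps(6))
  sim <- simulate_baro(spec)
  expect_gte(sim$truth$n_ramps, 6)
  for (k in seq_len(nrow(sim$truth$ramps))) {
    w <- sim$truth$ramps$start_beat[k]:sim$truth$ramps$end_beat[k]
    fit <- stats::lm(sim$beats$ibi_ms[w] ~ sim$beats$sbp_mmhg[w])
    expect_equal(unname(stats::coef(fit)[2]), 15, tolerance = 1e-10)
  }
  # zero gain leaves the IBI flat: no step reaches the 5-ms floor
  flat <- simulate_baro(baro_sim_spec(gain_ms_per_mmhg = 0, n_beats = 100))
  expect_true(all(abs(diff(flat$beats$ibi_ms)) < 5))
  expect_error(baro_sim_spec(n_beats = 5), class = "sc_validation_error")
})

test_that("PPG template extrema coincide with the declared fiducials", {
  spec <- ppg_sim_spec(n_pulses = 10, aS_mv = 2.0, aDic_mv = 1.0, aD_mv = 1.5)
  sim <- simulate_ppg(spec)
  expect_equal(sim$truth$onset_s, 0:9)
  # per-pulse term of the modified augmentation index from the generator amplitudes
  expect_equal((sim$truth$aD_mv[1] - sim$truth$aDic_mv[1]) /
               (sim$truth$aS_mv[1] - sim$truth$aDic_mv[1]), 0.5)
  # signal extrema sit within one sample of the truth table
  x <- sim$signal$values; fs <- sim$signal$fs
  for (k in c(2, 5, 9)) {
    i_sy <- round(sim$truth$systolic_s[k] * fs) + 1
    expect_equal(x[i_sy], max(x[(i_sy - 50):(i_sy + 50)]))
    i_no <- round(sim$truth$notch_s[k] * fs) + 1
    expect_equal(x[i_no], min(x[(i_no - 50):(i_no + 50)]))
  }
  expect_error(ppg_sim_spec(aD_mv = 2.5, aS_mv = 2.0), class = "sc_validation_error")
  expect_error(ppg_sim_spec(tS_s = 0.5, tC_s = 0.4, tD_s = 0.3, pi_s = 1.0),
               class = "sc_validation_error")
})

test_that("actigraphy generator honours the still window and the seed", {
  spec <- acti_sim_spec(total_duration_s = 3600, sleep_onset_s = 600, wake_s = 3000,
                        fs = 10)
  a <- simulate_actigraphy(spec)
  b <- simulate_actigraphy(spec)
  expect_identical(a$acc$x$values, b$acc$x$values)
  t <- signal_times(a$acc$x)
  still <- t >= 600 & t < 3000
  # still segment is gravity-dominated: tight norm; active segment is not
  nrm <- sqrt(a$acc$x$values^2 + a$acc$y$values^2 + a$acc$z$values^2)
  expect_lt(stats::sd(nrm[still]), 0.02)
  expect_gt(stats::sd(nrm[!still]), 0.05)
  expect_error(acti_sim_spec(sleep_onset_s = 100, wake_s = 50),
               class = "sc_validation_error")
})
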