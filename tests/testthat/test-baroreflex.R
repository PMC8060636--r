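# Beat extraction from pressure waves, sequence detection vs. an exhaustive
# oracle, and gain recovery.

make_pulse_train <- function(n_pulses, pi_s = 1.0, amp = 40, base = 80, fs = 200) {
  t <- seq(0, n_pulses * pi_s - 1 / fs, by = 1 / fs)
  sampled_signal(base + amp * pmax(sin(2 * pi * t / pi_s), 0)^2, fs = fs, unit = "mmHg")
}

test_that("systolic peaks of a uniform pulse train give constant SBP and IBI", {
  bp <- make_pulse_train(15)
  beats <- extract_beats(bp)
  expect_true(all(abs(beats$sbp_mmhg - 120) < 0.5))
  expect_true(all(abs(beats$ibi_ms - 1000) < 1000 / bp$fs * 1.5))
  expect_error(extract_beats(sampled_signal(rep(80, 3000), fs = 200)),
               class = "sc_quality_error")
})

test_that("collinear up-ramps yield one sequence with the exact slope", {
  beats <- list(sbp_mmhg = c(120, 122, 124), ibi_ms = c(800, 810, 820))
  s <- detect_sequences(beats)
  expect_equal(nrow(s), 1L)
  expect_equal(s$direction, "up")
  expect_equal(s$slope_ms_per_mmhg, 5.0)
  expect_equal(s$r, 1.0)

  # sub-threshold pressure steps gate the sequence out
  none <- detect_sequences(list(sbp_mmhg = c(120, 120.5, 121),
                                ibi_ms = c(800, 810, 820)))
  expect_equal(nrow(none), 0L)
  # sub-threshold IBI steps too
  none2 <- detect_sequences(list(sbp_mmhg = c(120, 122, 124),
                                 ibi_ms = c(800, 804, 808)))
  expect_equal(nrow(none2), 0L)
})

test_that("sequence detection matches exhaustive window enumeration", {
  for (seed in 1:30) {
    b <- random_beat_series(120, seed)
    got <- detect_sequences(b)
    want <- oracle_sequences(b$sbp_mmhg, b$ibi_ms)
    got <- got[order(got$start_index, got$direction), ]
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_index, want$start_index)
      expect_equal(got$length_beats, want$length_beats)
      expect_equal(got$direction, want$direction)
      expect_equal(got$slope_ms_per_mmhg, unname(want$slope_ms_per_mmhg),
                   tolerance = 1e-9)
    }
  }
})

test_that("negating both deviations leaves |slope| and validity unchanged", {
  b <- random_beat_series(200, 77)
  flipped <- list(sbp_mmhg = 240 - b$sbp_mmhg, ibi_ms = 1800 - b$ibi_ms)
  s1 <- detect_sequences(b)
  s2 <- detect_sequences(flipped)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(sort(abs(s1$slope_ms_per_mmhg)), sort(abs(s2$slope_ms_per_mmhg)),
               tolerance = 1e-9)
})

test_that("gain recovery: exact when noise-free, within 10% under noise", {
  for (gain in c(5, 10, 15, 25)) {
    for (noise in c(0, 2, 5)) {
      sim <- simulate_baro(baro_sim_spec(gain, n_beats = baro_beats_for_ramps(12),
                                         noise_sd_ms = noise,
                                         seed = 100 + gain + noise))
      est <- estimate_brs(sim$beats)
      expect_true(est$valid)
      if (noise == 0) {
        expect_equal(est$brs_ms_per_mmhg, gain, tolerance = 1e-9)
      } else {
        expect_equal(est$brs_ms_per_mmhg, gain, tolerance = 0.10)
      }
    }
  }
})

test_that("fewer than five sequences invalidates the estimate", {
  sim <- simulate_baro(baro_sim_spec(15, n_beats = baro_beats_for_ramps(4)))
  est <- estimate_brs(sim$beats)
  expect_equal(est$n_sequences, 4L)
  expect_false(est$valid)
  expect_true(is.na(est$brs_ms_per_mmhg))

  flat <- simulate_baro(baro_sim_spec(0, n_beats = 200))
  est0 <- estimate_brs(flat$beats)
  expect_false(est0$valid)
  expect_equal(est0$n_sequences, 0L)
})

test_that("beats recovered from a simulated pressure wave reproduce the gain", {
  sim <- simulate_baro(baro_sim_spec(12, n_beats = baro_beats_for_ramps(8)))
  # render the beat table as a pressure waveform: one raised-cosine pulse per
  # beat with the prescribed systolic amplitude and interval
  fs <- 250
  ibi_s <- sim$beats$ibi_ms / 1000
  onsets <- c(0, cumsum(ibi_s))
  total <- sum(ibi_s) + 1
  t <- seq(0, total, by = 1 / fs)
  x <- rep(70, length(t))
  for (k in seq_along(sim$beats$sbp_mmhg)) {
    seg <- t >= onsets[k] & t < onsets[k] + 0.35
    x[seg] <- 70 + (sim$beats$sbp_mmhg[k] - 70) * sin(pi * (t[seg] - onsets[k]) / 0.35)^2
  }
  beats <- extract_beats(sampled_signal(x, fs, unit = "mmHg"))
  est <- estimate_brs(beats)
  expect_true(est$valid)
  expect_equal(est$brs_ms_per_mmhg, 12, tolerance = 0.05)
})
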