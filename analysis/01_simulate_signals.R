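#!/usr/bin/env Rscript
# Generate one instance of every input class with known ground truth:
# an orthostatic RR series (with injected ectopy), a beat-wise SBP-IBI
# recording, a PPG pulse train, and a night of wrist actigraphy.
# Raw signal files go to scratch/ (they are bulky and fully reproducible);
# the ground-truth summary table goes to results/.

library(sleepcardio)
dir.create("results", showWarnings = FALSE)
dir.create("scratch/signals", showWarnings = FALSE, recursive = TRUE)
seed <- 1

rr <- simulate_rr(rr_sim_spec(ectopic_rate = 0.02, duration_s = 300, seed = seed))
write_interval_file(rr$beats, "scratch/signals/rr_intervals.txt")

baro <- simulate_baro(baro_sim_spec(gain_ms_per_mmhg = 15,
                                    n_beats = baro_beats_for_ramps(10),
                                    noise_sd_ms = 2, seed = seed))
ppg <- simulate_ppg(ppg_sim_spec(n_pulses = 60, seed = seed))
write_sampled_csv(ppg$signal, "scratch/signals/ppg.csv", channel = "ppg_mv")

acc <- simulate_actigraphy(acti_sim_spec(seed = seed))
write_sampled_csv(acc$acc, "scratch/signals/accelerometer.csv")

truth <- data.frame(
  quantity = c("rr_pLF_ms2", "rr_pHF_ms2", "rr_n_ectopic",
               "baro_gain_ms_per_mmhg", "baro_n_ramps",
               "ppg_mai_term", "ppg_pi_s",
               "sleep_onset_s", "sleep_wake_s"),
  value = c(rr$truth$pLF_ms2, rr$truth$pHF_ms2, length(rr$truth$ectopic_beats),
            baro$truth$gain_ms_per_mmhg, baro$truth$n_ramps,
            (ppg$truth$aD_mv[1] - ppg$truth$aDic_mv[1]) /
              (ppg$truth$aS_mv[1] - ppg$truth$aDic_mv[1]),
            1.0, acc$truth$sleep_onset_s, acc$truth$wake_s))
write_results_table(truth, "results/simulation_truth.csv")

message(sprintf("RR series: %d beats, %d ectopic pairs injected; truth pLF = %g, pHF = %g ms^2",
                length(rr$beats$intervals_ms), length(rr$truth$ectopic_beats),
                rr$truth$pLF_ms2, rr$truth$pHF_ms2))
message(sprintf("SBP-IBI: %d beats embedding %d ramps at gain %g ms/mmHg",
                length(baro$beats$sbp_mmhg), baro$truth$n_ramps, 15))
message(sprintf("PPG: %d pulses, per-pulse augmentation term %.3f; actigraphy: sleep %g-%g s",
                nrow(ppg$truth), truth$value[6], 1800, 27000))
message("signals in scratch/signals/, truth table in results/simulation_truth.csv")
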