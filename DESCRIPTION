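Package: sleepcardio
Title: Cardiovascular Autonomic Markers Under Partial Sleep Deprivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for cardiovascular autonomic markers
    recorded around partial sleep deprivation protocols: heart rate variability
    from orthostatic-test inter-beat intervals (ectopic-beat correction, RMSSD,
    Welch band powers in the LF and HF bands, normalized powers), sequence-method
    baroreflex sensitivity from continuous blood pressure, photoplethysmogram
    pulse delineation with a modified augmentation index averaged over the last
    hour of sleep, wrist-actigraphy sleep-window detection, and the study-level
    phase aggregation and Cohen's d effect sizes. Ships synthetic-signal
    generators with analytic ground truth so every stage is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
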