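Package: pulsefeat
Title: Landmark Detection and Feature Extraction for Arterial Blood
    Pressure and Photoplethysmography Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the five temporal landmarks of each cardiac cycle
    (systolic phase onset, systolic phase peak, dicrotic notch, diastolic
    phase peak, diastolic phase endpoint) in arterial blood pressure (ABP)
    and photoplethysmography (PPG) waveforms using an iterative envelope
    mean (IEM) decomposition of 4-second signal windows, and extracts a
    manifest of 852 per-cycle features spanning time-, statistical- and
    frequency-domain families. Includes artifact screening, Butterworth
    low-pass filtering and min-max normalization, a tolerance-based
    detector evaluation harness (sensitivity, positive predictive value,
    F1, error rate, Bland-Altman agreement), and a synthetic pulse-train
    generator with analytic ground-truth landmarks so the whole pipeline
    is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
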