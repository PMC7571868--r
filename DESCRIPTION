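Package: bcgfluct
Title: Resting-State Ballistocardiogram Waveform Fluctuation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the beat-to-beat morphological stability of the
    resting-state ballistocardiogram (BCG) with the waveform fluctuation
    metric at rest (WFMR): sliding-window ensemble averages of R-aligned
    heartbeats within 20-second epochs, pairwise mean square errors between
    the averages, and the natural log of their mean. Includes a synthetic
    multichannel generator (BCG, ECG with intrinsic/paced/PVC beats,
    beat-to-beat and cuff blood pressure, with ground-truth fiducials),
    FIR and stationary-wavelet preprocessing, Pan-Tompkins R-wave
    detection, rule-based beat typing and ECG delineation, reference
    interval features with linear QT correction, blood-pressure offset
    calibration, and cohort comparison via a one-sided Welch t-test and
    leave-one-subject-out classification.
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
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
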