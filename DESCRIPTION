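Package: eegcleanse
Title: Automated Cleaning of Mobile EEG Recorded During Full-Body Movement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated, hardware-independent pipeline for cleaning
    multichannel EEG recorded during full-body movement. Parses raw OpenBCI-style
    text recordings, synchronizes them to gameplay events and segments them by
    mini-game, screens out high-impedance, flatline, low-correlation and noisy
    channels, corrects transient motion artifacts with Artifact Subspace
    Reconstruction (ASR), applies duration-adaptive zero-phase high-pass FIR
    filtering, decomposes the signal with extended-infomax ICA on both the
    ASR-cleaned and filtered versions, and retains brain-related independent
    components through a hybrid four-criterion voting strategy over pluggable
    component classifications. Includes a validation-metric suite (spectral
    entropy, band power, SNR proxy, correlation to raw, effective rank, paired
    comparisons) and a synthetic-session generator with planted artifacts and
    ground truth so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
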