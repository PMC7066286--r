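Package: oddlock
Title: Individualized Phase-Locked tACS Pipelines for Oddball P300 Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studies that phase-lock
    transcranial alternating current stimulation (tACS) to the P300
    event-related potential elicited by a visual oddball task. Provides a
    synthetic oddball-EEG generator (delta/theta event-related oscillation
    embedded in 1/f background noise, blink artifacts, behavioral response
    stream), readers and writers for BrainVision and EDF+ recordings, online
    and offline preprocessing chains (zero-phase filtering, epoching, blink
    trial rejection, average reference, ICA-based blink cleanup),
    Morlet-wavelet event-related spectral perturbation (ERSP) maps,
    individualized stimulation-parameter estimation (P300 latency, ERO
    frequency, phase-locked wait duration), during-block stimulus scheduling,
    outcome extraction (P300 amplitude and latency, reaction-time mean and
    variability, omission and commission errors), and the group-level
    rank-sum / FDR / Spearman statistics, plus an orchestrator that runs a
    full two-group study end to end on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
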