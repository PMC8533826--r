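Package: speechsync
Title: Sensorimotor Synchronization Analysis for Natural Speech Tapping Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing finger-tapping experiments in which listeners
    synchronize with the perceived beat of looped natural-speech sentences.
    Reduces raw tap logs to per-syllable synchronization likelihood and
    asynchrony via Gaussian kernel density estimation, relative-threshold peak
    detection and windowed matching to annotated syllable-nucleus onsets;
    extracts amplitude-envelope rise-time, nucleus duration and relative
    intensity from stimulus audio; scores unpaced and paced tapping tasks
    (inter-tap intervals, asynchronies) and phoneme-monitoring responses
    (signal-detection d-prime); and provides the group-level statistical stage
    (Welch tests, pooled Cohen's d, mixed-effects model construction with
    backward interaction reduction, pairwise group contrasts, simulation-based
    power). A fully seeded synthetic-data generator emulates the experimental
    design so every stage is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
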