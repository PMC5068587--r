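Package: gcsr
Title: Goal-Conflict-Specific Rhythmicity Analysis for the Three-Staircase Stop-Signal Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a frontal EEG anxiety-process
    biomarker: goal-conflict-specific rhythmicity (GCSR) measured in a modified
    stop-signal task with three stop-signal-delay staircases. Provides the task
    schedule and staircase state machines, a race-model behavioural simulator,
    a synthetic EEG generator (pink noise, mains, eye blinks, injectable 4-12 Hz
    conflict bursts), blink-template preprocessing, Hanning-windowed spectral
    power extraction, the Stop-Go by SSD-quadratic contrast per frequency, and
    contrast-based group and personality statistics with forward stepwise
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
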