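Package: audbattery
Title: Simulation and Analysis of an Auditory Profiling Test Battery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation of a clinical auditory test battery:
    parametric stimulus synthesis (warble tones, threshold-equalizing noise,
    spectro-temporal ripple noise, dichotic and interaural-phase stimuli),
    adaptive psychophysical procedures (single-interval adjustment-matrix
    yes/no tracking with catch trials, 2-AFC frequency tracking, adaptive
    categorical loudness scaling, sentence-in-noise staircases), simulated
    listeners with configurable hearing profiles, outcome estimation
    (d-prime screening scores, loudness-function and psychometric-function
    fits, masking release), and test-retest reliability plus exploratory
    correlation/factor analysis of the resulting 26-variable outcome table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
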