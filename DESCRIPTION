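Package: reflexgait
Title: Cutaneous Reflex and Interlimb Coordination Analysis for Quadrupedal Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify phase- and task-dependent modulation of
    cutaneous reflexes and interlimb coordination during tied-belt and
    split-belt treadmill locomotion. Computes spatiotemporal gait parameters
    (cycle, stance and swing durations, step and stride lengths) from paw
    contact/liftoff events, circular measures of interlimb coordination
    (phase and gap intervals, symmetry indexes, resultant vector length,
    Rayleigh and Watson-Williams tests), and stimulus-evoked reflex responses
    against a baseline locomotor EMG (blEMG): response detection with
    confidence bands, latency classification (P1/N1, P2/N2, P3/N3), net
    reflex values and phase-modulation indexes, plus one-factor
    repeated-measures ANOVA with unadjusted pairwise comparisons. Includes a
    synthetic four-limb locomotor session generator with ground truth so the
    whole pipeline can be exercised and validated without recorded data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
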