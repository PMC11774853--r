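Package: rhythmelody
Title: Stimulus Generation and Signal-Detection Analysis for Relative
    Rhythm and Melody Perception Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for same/different experiments on relative rhythm and
    melody perception. Generates constrained random stimulus sets (snare
    rhythms on a 32nd-note tick grid, major-pentatonic melodies), applies
    single-event manipulations with compensation, classifies contour impact
    and framework conformity (Longuet-Higgins & Lee syncopation with
    phase-shift minimisation for rhythm, pentatonic key membership for
    melody), writes stimuli to Standard MIDI Files, WAV audio and manifest
    CSVs, simulates trial-level responses from an equal-variance Gaussian
    observer over the full balanced design, and analyses trial tables with
    pooled signal-detection measures (d-prime under a reminder-design
    scaling, bias c, percentage correct) and cross-domain regression of
    melody on rhythm performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
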