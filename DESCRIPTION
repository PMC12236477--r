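Package: reverie
Title: Music-Evoked Memory Reactivation in Naturalistic fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cross-group pattern-reinstatement analysis for naturalistic
    movie-watching fMRI with a repeated-music manipulation. Implements
    scene-boundary consensus annotation, mega-scene construction under a
    strictly-earlier cue-pairing rule, permutation-z reactivation scoring
    against a leave-one-out baseline, remembered-versus-forgotten
    subsequent-memory statistics with parcel-based searchlights and FDR
    correction, spatial intersubject correlation as an encoding-strength
    control with sequential residualization, music versus no-music
    condition contrasts, and a seeded synthetic-data generator that plants
    scene signatures, encoding-strength variation, cue-evoked
    reinstatement, and recall outcomes so the whole pipeline can be
    exercised and calibrated without real fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
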