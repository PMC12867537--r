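Package: StrokeRecovNet
Title: EEG Biomarker Modelling of Upper-Extremity Motor Recovery After Stroke
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts follow-up upper-extremity Fugl-Meyer (FMA-UE) scores
    after stroke from resting-state EEG. Implements a 221-feature biomarker
    extractor (Welch band powers, delta/alpha and (delta+theta)/(alpha+beta)
    ratios, pairwise-derived brain symmetry indices, individual alpha
    frequency, imaginary-coherency functional connectivity with
    proportionally thresholded weighted graph metrics), the proportional
    recovery rule baseline, ReliefF/mRMR feature selection, a feed-forward
    regression network evaluated under nested leave-one-subject-out
    cross-validation, feature-consistency scores, and a synthetic cohort
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
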