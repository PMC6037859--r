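Package: synctoj
Title: Simulation and Analysis of Audiovisual Synchrony and Temporal Order
    Judgment fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how synchrony judgments (SJ) and temporal
    order judgments (TOJ) about audiovisual stimuli are represented in
    behavior and in BOLD fMRI. Implements Gaussian and cumulative-Gaussian
    psychometric fitting with derivation of the point of subjective
    simultaneity (PSS) and temporal integration window (TIW), goodness-of-fit
    classification of TOJ ability, constraint-satisfying mixed
    block/event-related fMRI design generation with efficiency-based
    optimization over random candidate sequences, two-timescale
    (sustained plus transient) general linear model estimation with
    discrete-cosine high-pass filtering and AR(1) prewhitening, and
    voxelwise repeated-measures ANOVA with permutation-based cluster-extent
    FDR inference. A synthetic-data module generates behavioral response
    tables and 4D BOLD runs with known ground truth so the full pipeline is
    testable without any scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
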