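Package: tepscatter
Title: TMS-EEG Evoked Potentials, Beamformer Source Imaging and
    Significant Current Scattering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-pulse TMS-EEG effective
    connectivity studies. Provides artifact suppression for
    stimulus-locked EEG (pulse-window excision, decay regression,
    zero-phase filtering, trial and channel rejection, average
    referencing), sensor-level TMS-evoked potential (TEP) component
    quantification, an analytic three-shell spherical forward model with
    LCMV beamformer source projection, max-statistic permutation masking
    of post-stimulus source activity, distance-weighted significant
    current scattering (SCS) over default-mode, executive-control and
    salience network nodes, and the group statistics used to compare
    clinical cohorts. A seeded synthetic cohort generator produces
    BrainVision-format recordings with known source circuits and
    covariate structure so that every stage of the pipeline can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
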