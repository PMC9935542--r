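Package: rankcurve
Title: Expression-Ranked Connectivity Correlation Curves for Imaging Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links genetic and pharmacological effects on resting-state
    functional connectivity through regional gene-expression rankings.
    Provides first-level ROI-to-ROI Fisher-z connectivity, per-edge
    allele-dose general linear models and paired pharmacological contrasts,
    donor-normalized regional marker-gene expression profiles mapped onto a
    brain parcellation, nested expression-ranked correlation curves with
    AUC permutation inference, functional network connectivity tests with
    data-driven hierarchical clustering, symptom-domain multivariate tests,
    and a synthetic-data generator that reproduces the statistical
    structure of cohort, pharmaco-fMRI crossover, and postmortem
    expression inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
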