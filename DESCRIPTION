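Package: eegconnectome
Title: Weighted Brain-Network Analysis of High-Density Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds absolute-Pearson-correlation functional connectivity
    networks from high-density (256-channel) resting-state EEG and compares
    weighted graph metrics (clustering coefficient, strength, betweenness
    centrality) across the Alzheimer's disease continuum (healthy controls,
    subjective cognitive decline, mild cognitive impairment, dementia) at
    whole-head and parietal scope. Includes a latent-factor synthetic cohort
    generator with analytically known connectivity structure, a preprocessing
    chain (Butterworth band-pass, fixed-window segmentation, amplitude-based
    artifact rejection, bad-channel interpolation, average re-referencing),
    group inference (one-way ANOVA, pooled t tests, Bonferroni correction),
    and ROC-based group discrimination with Youden-optimal thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
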