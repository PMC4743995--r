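Package: saltmet
Title: Cross-Species Metabolomics of Hyperosmotic Salt Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nontargeted flow-injection metabolomics of
    hyperosmotic salt stress across diverse organisms. Covers estimation of
    maximum exponential growth rates and sigmoidal dose-response fitting of
    inhibitory salt concentrations (IC10/IC25/IC50); accurate-mass annotation
    of centroided ion tables against organism-restricted compound libraries,
    including deprotonated and 13C-isotopologue species and logP-based routing
    of polar and nonpolar extracts; quantile normalization, log2 fold-changes
    versus unstressed controls, pooled-variance t-tests with Storey-Tibshirani
    q-value false discovery rate control, and cross-species baseline Z-scores;
    global response comparison by principal components, Cityblock cladograms,
    Jukes-Cantor sequence distances and Mantel correlation of distance
    structures; a four-way ANOVA factor screen and a salt-tolerance
    correlation screen for hit finding; and a synthetic-data generator that
    emits a full study with machine-readable ground truth so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    limma,
    vegan,
    ape,
    phangorn,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
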