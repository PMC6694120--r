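Package: galcomb
Title: Combinatorial Genetics of the Yeast GAL Switch from Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for combinatorially complete mutant
    libraries of the yeast galactose-switch regulators GAL3, GAL80 and GAL4.
    Turns per-cell flow-cytometry event tables (or a seeded synthetic
    emulation of the study design) into per-sample expression summaries and
    Malthusian growth rates; classifies paired glucose/galactose expression
    distributions into phenotypic classes with a built-in HDBSCAN*
    implementation plus deterministic curation and rescue; predicts
    double-mutant growth under a multiplicative null and expression-class-mean
    models with standard-error propagation, variance partitioning and
    downsampled cross-validation; and calls the dependency of each
    GAL4-GAL80 background on the GAL1 and GAL3 galactose sensors via
    Welch/one-sample t-tests with Benjamini-Hochberg FDR control and a
    logistic leakiness null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
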