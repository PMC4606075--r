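Package: maplsc
Title: Imbalanced Multiclass PLS Classification and Herbal Formula Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing small, imbalanced clinical case tables of
    the kind collected in Traditional Chinese Medicine practice. The core
    is MAPLSC, a multiclass classifier built from one-versus-one
    asymmetric partial least squares classifiers whose decision boundary
    is shifted by the class score dispersions, with per-pair sigmoid
    posterior calibration and a simplified pairwise-coupling combination.
    Also included: macro/micro-averaged evaluation with a stratified
    cross-validation harness and reference baselines, Apriori frequent
    itemset mining of herbal prescriptions with core-formula cutoff
    heuristics, information-gain symptom ranking, a symptom-to-formula
    recommendation pipeline, readers and writers for CSV, ARFF and
    transaction files, and seeded generators of synthetic clinical case
    and prescription data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    foreign,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
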