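Package: connectopath
Title: Weighted Structural Connectome Topology and Outcome Prediction
Version: 1.0.0
Authors@R: person("Connectopath", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Graph-theoretical analysis of structural brain connectomes:
    proportional-threshold sweeps over weighted region-by-region
    tractography matrices with AUC aggregation of global efficiency,
    characteristic path length, clustering and nodal local efficiency;
    univariate group inference with Benjamini-Hochberg FDR control;
    linear support-vector classification and regression of diagnosis,
    treatment response and symptom severity under leave-one-out
    cross-validation with permutation testing; and a synthetic-cohort
    generator with planted subcortical effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
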