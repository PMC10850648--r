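Package: airdstrat
Title: Immunophenotype-Based Stratification of Autoimmune Rheumatic Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cohort-wide analysis of flow-cytometry immunophenotypes across
    autoimmune rheumatic diseases (AIRDs). Implements normalisation of
    immune-cell-type counts by the total viable PBMC denominator, confounder
    residualisation, hierarchical clustering at three resolutions (cell types,
    diseases, patients) with admissibility-constrained selection of the cluster
    number, a stratified-subsampling concordance check of cluster stability,
    correlation / inverse-distance / stepwise-logistic network layers, and
    downstream association testing (patient-cluster heterogeneity, cluster
    versus clinical features, polygenic-risk-score versus phenotypes). A
    synthetic cohort generator with planted group, cluster, clinical and PRS
    effects makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
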