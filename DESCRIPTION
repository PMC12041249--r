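Package: covnetclust
Title: Covariate-Adjusted Network-Based Clustering of Binary Genomic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based clustering of patients from binary mutation and
    cytogenetic profiles together with clinical covariates, using a mixture of
    cluster-specific Bayesian networks. Cluster-independent covariates (such as
    age or sex) are restricted to outgoing edges and conditioned on in the
    membership probabilities, so that clusters reflect mutational patterns
    rather than demographics. Includes score-based structure learning with
    modality-direction constraints and prior-knowledge edge penalties,
    preprocessing rules for clinical cohorts (prevalence filtering, median
    discretization, blast binning), a synthetic cohort generator, cluster
    stability assessment via the adjusted Rand index, multidimensional scaling
    of per-sample network fit, and entropy-based node statistics for
    cluster-network summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
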