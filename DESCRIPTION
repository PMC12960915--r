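Package: omicsweave
Title: Multi-Omics Integration, Method Comparison and Consensus Feature
    Ranking Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A harness for integrative analysis of multi-omics experiments.
    Imports per-omics measurement matrices together with samples and features
    metadata (CSV, GFF3/GTF), provides preprocessing diagnostics, NIPALS
    principal component analysis tolerant of missing values with PCA-based
    imputation, common transformations and variability-based or supervised
    feature prefiltering. Native latent-variable integration methods are
    included (two-block sparse partial least squares, its discriminant form,
    and a multi-block consensus PCA) alongside an adapter interface for
    external tools. All results are converted to a standard dimension
    reduction format from which per-feature importance scores, silhouette
    based group-separation diagnostics, feature-set enrichment, cross-method
    latent-dimension correlations and consensus feature rankings are derived.
    A make-like pipeline engine with content-hash invalidation and derived
    per-step seeds makes analyses reproducible end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    igraph,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
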