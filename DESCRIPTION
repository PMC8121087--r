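Package: protacclim
Title: Distribution-Aware Differential Proteomics with Bootstrapped Cluster
    Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for isobaric-label (TMT) quantitative
    proteomics of factorial experiments, built around a barley root-meristem
    cold-acclimation design. Provides pooled-channel normalization and
    evidence filtering, per-protein distribution fingerprinting in the
    (squared skewness, kurtosis) plane for GLM link selection, eight-regressor
    two-factor differential abundance with Benjamini-Hochberg FDR control,
    Pearson-correlation average-linkage clustering with multiscale-bootstrap
    approximately-unbiased (AU) support, K-means partitioning, random-forest
    and PLS-DA variable importance ranking, Needleman-Wunsch global alignment
    for cross-species ribosomal-protein paralog assignment, and BCA protein
    content statistics. A synthetic-data module generates every input with
    recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    multcomp,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
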