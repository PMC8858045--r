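Package: dgnet
Title: Disease Gene Network Analysis and Drug Repurposing from
    Co-Expression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A config-driven pipeline for inferring disease-associated
    genes and candidate repurposable drugs from gene expression and
    protein interaction data. Builds weighted gene co-expression
    networks (soft-thresholded adjacency, topological overlap, module
    detection via average-linkage clustering and eigengene merging),
    selects disease-associated modules by module-trait correlation,
    eigengene group differences and disease-gene over-representation,
    filters core genes by module membership and per-gene ROC AUC,
    computes disease-specific interactome statistics (disease-neighbor
    counts and ratios, shortest-path ratios) against permutation nulls,
    screens drugs by network proximity z-scores with an empirical
    reference distribution, and evaluates a small-panel support vector
    machine diagnostic classifier by stratified cross-validation.
    Includes generators for synthetic expression matrices with planted
    correlated modules, scale-free interactomes with locality-clustered
    disease genes, and drug-target sets at controlled proximity, so
    every inference step can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
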