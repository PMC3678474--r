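Package: pdthreat
Title: Projected Phylogenetic Diversity Loss Under Extinction Threats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how phylogenetically clustered extinction threats
    prune evolutionary history from a clade. Provides Faith's phylogenetic
    diversity (PD) on rooted ultrametric time trees, projected PD loss under
    binary threat scenarios relative to random-extinction null models
    (percent difference in expected PD), the D statistic for phylogenetic
    clustering of binary traits with permutation and Brownian-threshold
    nulls, tree-shape statistics (gamma, Colless) with Yule-model nulls, and
    cross-category regressions linking clustering to PD loss. Includes a
    synthetic generator of coral-like time-tree samples and threat tables
    with controlled shape, prevalence and clustering, so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
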