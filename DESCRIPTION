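Package: stagenet
Title: Stage-Specific Hub-Gene Coexpression Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds hub-gene-centred coexpression gene sets per tumour stage
    from RSEM-normalized expression matrices in the Broad Firehose dialect,
    tracks their rewiring across stage transitions (Jaccard similarity and
    lost/conserved/acquired gene classification), extracts stage-consistent
    and cross-cohort-common coexpressed genes, and screens candidates for
    diagnostic (tumour versus normal) and prognostic (quartile-split
    Kaplan-Meier with log-rank) value. Includes promoter-methylation
    comparisons on beta-values and a seeded synthetic-cohort generator with
    planted coexpression modules, expression shifts, methylation differences
    and survival effects, so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
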