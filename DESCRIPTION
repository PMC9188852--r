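Package: causaltox
Title: Causal Drug-Target Profiling and Network Enrichment for Toxicity Compound Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds harmonized causal (positive/negative/unspecified/inactive)
    drug-to-protein profiles from heterogeneous database exports (ChEMBL-style
    mechanism and assay records, IUPHAR interactions, DrugBank action tables),
    mines assay descriptions for directional keywords under a pChEMBL activity
    cutoff, removes cross-source contradictions, restricts profiles to
    tissue-expressed proteins, contrasts a toxic against a non-toxic compound
    group with a significance quotient, assembles a confidence-weighted protein
    network with a directed causal overlay from SIGNOR-format records, and runs
    topology-based pathway enrichment (random walk with restart, XD-style
    deviation scores, one-sided Fisher tests with Benjamini-Hochberg
    correction). Includes a deterministic synthetic-fixture generator with
    planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
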