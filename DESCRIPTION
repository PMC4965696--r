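Package: modulecover
Title: De Novo Pathway Enrichment by Module-Cover Subnetwork Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts connected subnetworks enriched for phenotype-active
    genes from biological interaction networks and binary indicator
    matrices, following the module-cover approach with individual (INES)
    and global (GLONE) node-exception models.  Includes greedy and exact
    extraction, border-exception-node filtering, four network-perturbation
    strategies (node-label permutation, degree-preserving rewiring, node
    removal, edge removal), Jaccard-based robustness and gold-standard
    validation analyses, and a planted-module synthetic instance generator
    for offline benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
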