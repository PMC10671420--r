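Package: coexmod
Title: Weighted Gene Co-Expression Modules and Candidate-Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted gene co-expression networks from RPKM expression
    matrices (Pearson similarity raised to a soft threshold chosen by
    scale-free topology fit), derives the topological overlap matrix, detects
    and merges co-expression modules via hierarchical clustering and module
    eigengenes, tests modules for over-representation of phenotype gene sets
    and chromosome-region gene sets with Fisher's exact test, and prioritizes
    candidate genes by intramodular connectivity, module membership (kME) and
    haploinsufficiency (pLI). Ships a factor-model synthetic-data generator
    with planted modules and planted gene-set enrichment so the whole pipeline
    is testable without external data, and a deterministic end-to-end pipeline
    driver with structured configuration and checksummed run artifacts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
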