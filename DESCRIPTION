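Package: shapegenet
Title: Linking Cell Morphology to Transcription, Networks and Patient Outcome
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An image-omics analysis pipeline for breast cancer cell lines:
    screens genes whose expression correlates with single-cell morphology
    summaries (Spearman, FDR), assembles a shape-gene interaction network from
    STRING-style interaction tables with degree/closeness/stress/betweenness
    centralities and feature-to-transcription-factor path extraction,
    classifies regulators and effectors of transcription factors from a
    gene-knockdown expression panel (hypergeometric target overlap), derives
    morphological and NF-kB-response metagenes by forward sequential feature
    selection, and associates metagene scores with tumor grade
    (Jonckheere-Terpstra) and disease-specific survival (Kaplan-Meier,
    log-rank, Cox). Includes a synthetic-data generator with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
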