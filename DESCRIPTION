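Package: coexcross
Title: Co-Expression Modules, Risk-Gene Enrichment, and Cross-Tissue Module Crosstalk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated two-tissue transcriptome analysis pipeline for
    case/control brain RNA-seq studies. Screens differentially expressed
    genes with a negative-binomial Wald test, seeds a high-confidence
    protein-protein interaction subnetwork with the DEGs and their
    interactors, detects weighted co-expression modules via soft-thresholded
    correlation and topological overlap, scores modules for risk-gene
    enrichment with hypergeometric tests, identifies pivot transcriptional
    and post-transcriptional regulators of the modules, and tests
    cross-tissue module pairs for excess protein-protein interactions with a
    permutation null. Ships a synthetic-data generator with planted modules,
    planted differential expression, planted pivot regulators and planted
    crosstalk pairs so that every stage can be validated by
    parameter-recovery experiments without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
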