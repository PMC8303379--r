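Package: lncImmNet
Title: Immune-Associated lncRNA Screening from Bulk RNA-seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-deterministic pipeline from a gene-level count
    matrix to immune-associated long non-coding RNAs (imm-lncRNAs): trimmed
    mean of M-values (TMM) normalization and negative-binomial exact tests for
    differential expression, short time-series model-profile clustering with a
    permutation test, hypergeometric over-representation analysis,
    single-sample GSEA (ssGSEA) immunocyte infiltration scoring, and
    thresholded Pearson correlation networks assembled into a multilayer
    lncRNA-immunocyte-GO network with Sankey and GraphML export. A
    negative-binomial simulator with planted ground truth (differential genes,
    latent cell-type abundances driving marker genes, lncRNAs coupled to cell
    abundances) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
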