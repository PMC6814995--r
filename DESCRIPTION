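Package: nmomics
Title: Integrative Multi-Omics Co-Expression Network Analysis for
    Nanomaterial Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to categorize nanomaterial treatments as active or passive
    from multi-omics in vitro screens (global proteomics, targeted
    metabolomics, SH2 phosphoprotein profiling) and to nominate key-driver
    biomarker candidates. Implements replicate filtering, log2 fold-change
    statistics with Benjamini-Hochberg adjustment, cross-omics scaling and
    hierarchical clustering, weighted co-expression network construction
    (soft-threshold adjacency and topological overlap), module detection with
    eigengene merging, module-trait correlation, gene significance and module
    membership, and threshold-based key-driver selection. A synthetic-data
    generator with planted modules, traits and drivers provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
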