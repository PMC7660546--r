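Package: cnedrift
Title: Relaxed Selection on Conserved Non-Coding Elements Across a Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects relaxed purifying selection on conserved non-coding
    elements (CNEs) and coding loci across a species phylogeny. Implements
    Felsenstein pruning likelihoods under JC/HKY, per-locus maximum-likelihood
    branch lengths on a fixed topology, relative evolutionary rates (RER) with
    sqrt transform and heteroskedasticity-aware weighting, branch-specific
    acceleration likelihood-ratio tests, GREAT-style basal-plus-extension
    regulatory-domain assignment of CNEs to genes, ontology enrichment by
    bootstrap resampling (Z-scores and SUMSTAT on fourth-root likelihood
    ratios) with FDR control, a truncating-variant screen with read-support
    rules and pleiotropy scoring, and erythrocyte shape quantification
    (circularity, solidity) from cell-mask images. A synthetic-data module
    generates every input with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    IRanges,
    S4Vectors,
    igraph,
    Biostrings,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
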