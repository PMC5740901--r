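Package: peakfates
Title: Peak-Fate and Expression-Category Analysis for Mutually Exclusive
    Chromatin-Remodeler Subunits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies ChIP-seq peak fates (lost versus retained/gained)
    of one SWI/SNF ATPase subunit after depletion of its mutually
    exclusive sibling, cross-classifies lost regions by the sibling's
    fate in the same knockdown (Groups 1-4), links peaks to nearest-TSS
    direct target genes, categorizes doubly regulated genes into
    concordant and antagonistic quadrants, and quantifies double-knockdown
    rescue of antagonistic genes. Includes blacklist filtering, recursive
    peak merging, chromatin-state annotation, coverage metaprofiles at
    peak midpoints and TSS, a statistical layer (exact Wilcoxon
    signed-rank, 2x2 chi-square, Benjamini-Hochberg), and a synthetic-data
    generator with exactly planted ground truth so every stage of the
    pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
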