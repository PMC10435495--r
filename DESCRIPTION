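Package: l1regkit
Title: Gene-Set, Interaction and Positional Statistics for LINE-1 Regulatory RNA Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for studying transposable-element derived regulatory
    RNAs in neural development. Provides a resampling gene-set overlap
    enrichment test with Benjamini-Hochberg correction, gene-set concordance
    metrics (Jaccard index, Fisher's exact overlap, consistent and
    directional differential-expression filters), a protein-RNA interaction
    ranking score combining normalized propensity, RNA-binding-protein
    propensity and motif evidence, positional co-occurrence statistics for
    RNA G-quadruplexes and predicted binding sites (binning, relative-position
    density, hypergeometric overlap test with a minus-strand control),
    an end-to-end k-mismatch shRNA off-target scanner with expressed-gene
    classification, and the small quantification formulas of qPCR-based work
    (delta-delta-Ct knockdown, radial cell distributions, bisulfite
    peak-height methylation, subcellular fraction percentages). A seeded
    synthetic-data module generates every input with machine-readable planted
    truth so that all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
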