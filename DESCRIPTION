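Package: heritex
Title: Heritable Transcriptomic Variation in Structured Inbred Populations
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heritable transcriptomic variation in
    structured panels of inbred lines: broad-sense heritability of gene
    expression from replicated genotypes, expression and splicing QTL mapping
    with peak consolidation and cis/trans classification, percent-spliced-in
    (PSI) intron quantification, LD-based colocalization of eQTL and sQTL
    signals, independent component analysis of expression matrices for latent
    co-expression module discovery with GWAS enrichment, and two-population
    selective-sweep scans (windowed Weir-Cockerham Fst, XP-CLR composite
    likelihood, nucleotide-diversity QC). Includes a synthetic-data generator
    with known ground truth (Balding-Nichols population structure, planted
    cis/trans regulatory effects, splicing QTLs and sweep windows) for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
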