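Package: epiDiverge
Title: Genetic Versus Epigenetic Population Divergence from
    Reduced-Representation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compares genetic and epigenetic divergence among natural
    populations sampled with reduced-representation sequencing. Implements
    per-locus Weir-Cockerham theta (F_ST) with RAD-style locus filters,
    100-bp tiled differential-methylation calling from bismark coverage
    files (binomial logistic likelihood-ratio tests with
    Benjamini-Hochberg correction), the P_ST variance-partition statistic
    for CpG methylation, promoter/UTR/exon/intron/downstream/intergenic
    feature classification with random-tile null sets, salinity
    stress-index profiling, and a calibrated synthetic-data generator
    (Balding-Nichols genotypes, hierarchical methylomes, gene models,
    salinity series) that emulates a four-population oyster study design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
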