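Package: soypopdiv
Title: Comparative Population Genetics of Two Cultivated-Soybean Gene Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for comparing two gene
    pools of a mostly-inbred diploid crop from a biallelic SNP panel:
    per-locus diversity statistics (MAF, gene diversity, PIC, observed
    heterozygosity), linkage-disequilibrium decay, Rogers distance and
    Loiselle kinship, neighbor-joining clustering, principal component
    analysis and Evanno delta-K post-processing, AMOVA and Weir-Cockerham
    FST with sliding-window outlier scans, and a three-pronged selection
    scan (allele-frequency t statistic, population-specific alleles,
    EigenGWAS with genomic control). A seeded Balding-Nichols two-population
    simulator with planted selected loci and truth tables makes every stage
    verifiable without external genotype data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
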