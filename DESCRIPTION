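Package: polykit
Title: Subgenome Dynamics and Population Genomics of Allopolyploids
Version: 0.1.0
Authors@R:
    person("polykit", "developers", email = "polykit@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for recently formed allotetraploid genomes with
    two resolvable subgenomes. Detects homoeologous exchange from subgenome
    read-depth ratios (windowed allele balance, dosage segmentation and 3:1
    chi-squared tests), summarizes post-polyploidy fractionation from syntelog
    tables (retention tracks, deletion-run spectra, intergenic gap profiles,
    retention-class enrichment, Ks density peaks, LTR insertion ages), computes
    a population-genetic statistic suite (windowed nucleotide diversity and
    Tajima's D, per-gene Weir-Cockerham FST, SNP filters, outgroup
    polarization, site frequency spectra, F3 with weighted block jackknife and
    Z-score FDR adjustment, windowed D/f_d introgression scans), and assesses
    subgenome expression bias on syntelog pairs after removal of exchanged
    regions. A synthetic-data generator with recorded ground truth emulates
    all required inputs so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
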