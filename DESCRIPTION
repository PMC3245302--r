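Package: dermadup
Title: Discovery and Characterization of an Inverted Duplication Driving
    Dermal Hyperpigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully synthetic-data-driven pipeline for discovering a
    complex structural variant of the kind that causes Fibromelanosis (dermal
    hyperpigmentation) in the chicken: an inverted duplication joining two
    genomic regions separated by hundreds of kilobases. Provides generators for
    SNP-array cohorts (Log R ratios and genotype calls over a ~1.7 Mb locus),
    pooled mate-pair sequencing libraries and qPCR Ct tables, each with a
    machine-readable truth record; copy-number detection by circular binary
    segmentation and group-wise Log R ratio differencing; a fixed-heterozygosity
    and shared-haplotype scan; 1 kb read-depth windows, depth-normalized log2
    fold change and a discordant mate-pair candidate structural-variant rule
    with inversion flagging; breakpoint refinement with microhomology calling;
    exhaustive enumeration of locus architectures from junction evidence with
    in-silico PCR and recombinant-offspring elimination; and delta-delta-Ct
    genomic copy-number and relative-expression quantification with
    standard-curve quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
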