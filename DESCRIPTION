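Package: editqc
Title: Quality Control for Genome-Edited Crop Lines
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-editing quality control analyses for CRISPR/Cas9-edited
    plants. Implements alignment-free transgene detection from whole-genome
    shotgun reads (per-position k-mer counts on the transformation
    construct, an exact conditional enrichment test against a negative
    control with Benjamini-Hochberg FDR adjustment, run calling with
    shared-background masking, and presence/absence/residual-fragment
    classification), exhaustive mismatch scanning for candidate off-target
    sites under an IUPAC PAM constraint, amplicon-based indel genotyping
    with zygosity classification (wild type, homozygous, heterozygous,
    biallelic, mosaic), Dunnett's many-to-one comparisons computed from
    group summary statistics by deterministic quadrature, and seeded
    synthetic-data generators so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    pracma,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
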