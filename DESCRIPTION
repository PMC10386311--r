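Package: rdnavar
Title: Simulation and Analysis of 45S rDNA Copy Number and ETS Variant Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying 45S ribosomal DNA diversity from short-read
    data. Simulates genomes carrying tandem 45S rDNA arrays of known copy
    number, External Transcribed Spacer (ETS) variant composition and
    polymorphisms, together with paired-end reads; recovers copy number by
    the depth-ratio method (mean rRNA-gene depth over mean single-copy
    background depth); profiles per-position alternative-allele frequencies
    along the rDNA unit with a within-individual detection threshold; calls
    3'ETS and 5'ETS genotypes from relative variant abundances with a
    declarative variant catalog and in-silico PCR; and summarizes cohorts
    (genotype frequencies, per-site composition, diversity by altitude
    group).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
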