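Package: iesretention
Title: IES Retention Scoring and Cross-Generational Transition Analysis
    for Programmed DNA Elimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for developmental plasticity in ciliate
    programmed DNA elimination. Computes per-locus Internal Eliminated
    Sequence (IES) Retention Scores from junction-spanning read counts,
    detects significant upward or downward retention transitions between
    consecutive sexual generations with a confidence-interval-referenced
    exact binomial procedure, annotates premature termination codons
    introduced by IES retention under the ciliate nuclear genetic code,
    and stratifies loci by gene-expression quartile, IES size class,
    genomic location and epigenetic-control class for contingency and
    rank statistics. A deterministic synthetic-data generator produces
    ground-truth genomes, annotations, expression tables and
    per-condition read counts so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
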