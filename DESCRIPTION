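Package: intronaut
Title: Detection of Self-Splicing Introns in Bacterial tRNA Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds group I (and group II) self-splicing introns that interrupt
    bacterial tRNA genes, a class of feature that standard tRNA annotation
    tools frequently miss or mis-assign. Starting from covariance-model hit
    tables and genome sequences, the package enumerates candidate splice
    boundaries under the group I rules (5'-exon terminal U, intron-terminal
    omega-G, splice junction inside the 7-nt anticodon loop of a valid
    cloverleaf fold), disambiguates competing boundary frames by local
    alignment against intron-less tRNA homologs, classifies the host locus of
    each intron (tRNA, rRNA, tmRNA, CDS, IStron-like, unknown), annotates
    homing-endonuclease ORFs, and aggregates survey statistics such as
    per-phylum retention rates and insertion-site matrices. A synthetic-genome
    generator with full ground-truth bookkeeping makes every stage testable
    without external downloads.
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
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
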