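Package: csbt
Title: cDNA Amplicon Sequence-Based Typing for HLA Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements cDNA sequence-based typing (cSBT) of HLA genes from
    multiplexed amplicon reads: MID demultiplexing, stringent length
    trimming, 100%-identity read mapping against a reference allele database
    with typed match conditions, forward-keyed reference restriction,
    class I and class II match-matrix joins, stringent and low-stringency
    genotype calling, and putative novel allele detection with variant
    annotation. Also provides the companion in-silico amplicon design tools
    (variability profiles, conserved primer windows, typing-resolution
    prediction) and a seeded read simulator so the whole pipeline is
    testable without external reference downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
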