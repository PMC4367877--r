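Package: telandscape
Title: Headless Analysis of Transposable Element Landscapes in Annotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads annotated genomes (GenBank, EMBL or a native tabular
    dialect) together with repeat-hit files (RepeatMasker, Censor, BLAST
    tabular, Repet or native TSV) and computes reproducible tables and plots
    describing the genomic landscape of transposable element (TE) copies:
    per-chromosome location tracks and occurrence curves, genome-wide family
    frequencies, copy-size distributions and coverage proportions, TE-gene
    distance classification (proximal promoter, proximal 3' end, within gene,
    intergenic), Gene Ontology slim distributions of TE-neighboring genes,
    and a master TE-gene feature table with cross-organism couple counts.
    Includes a deterministic synthetic-genome generator with planted ground
    truth for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
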