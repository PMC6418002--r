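Package: microevo
Title: Comparative Microevolution Analysis of Giant Virus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying microevolution between near-identical giant
    virus genomes, built around the pandoravirus model system. Implements
    pan/core-genome accumulation curves over all genome combinations,
    dating of strain-unique gene creation on a labeled phylogeny via
    translated (six-frame) searches of non-coding regions, compositional
    signatures of newborn genes (Codon Adaptation Index, G+C content,
    length, amino-acid composition chi-square), Nei-Gojobori (1986)
    pairwise dN/dS with node-stratified aggregation, non-coding RNA
    calling and antisense/intergenic classification, detection of
    terminal palindromes and terminal-inverted-repeat transposons, and a
    forward genome-evolution simulator with de novo gene birth from
    intergenic protogenes that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
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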