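Package: pgmap
Title: Proteogenomic Mapping of Peptides onto Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps experimentally observed peptides exactly onto a nucleotide
    database translated in all six reading frames under a user-selected NCBI
    genetic code, using a from-scratch Aho-Corasick multi-pattern matcher.
    Each match is extended into an expressed Protein Sequence Tag (ePST)
    under prokaryotic start/stop rules, eukaryotic signal-bounded rules
    (canonical GT/AG splice signals or GeneSplicer predictions), or by a
    fixed nucleotide length. Results are emitted as tidy tibbles and written
    as ePST FASTA, a detailed TSV report, and a GFF3 evidence track. A
    synthetic fixture generator plants peptides inside ORFs with known
    boundaries for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
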