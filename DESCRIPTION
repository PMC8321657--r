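Package: regmut
Title: Candidate Functional Noncoding Mutations in Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate functional noncoding somatic mutations in
    cancer genomes.  Builds a trinucleotide-context-preserving simulated
    mutation background, scans a genome for transcription factor motifs with
    exact log-odds p-values, scores mutated motifs with cell-type-matched
    functional annotations, merges them into mutated regulatory elements
    tested against the local simulated background and a Poisson burden model,
    tests per-TF and per-motif-position mutation enrichment, compares
    96-context mutational signatures between regulatory and other mutations,
    and associates elements with genes, expression, methylation and pathways.
    Includes a synthetic-data generator with planted ground truth so the whole
    pipeline is testable at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
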