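Package: memir
Title: MEM-Based miRNA Quantification and m6A Motif Discovery from Small-RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing N6-methyladenosine (m6A) in
    mature microRNAs from small-RNA sequencing experiments. Covers 3' adapter
    trimming with an error-tolerant placement search, assignment of candidate
    reads to a duplicate-collapsed mature-miRNA catalog via maximal exact
    matches (MEMs), reads-per-million normalization, threshold-based calls of
    expressed, differential (knockdown versus scrambled control) and methylated
    (m6A-IP versus IgG-IP enriched) miRNAs, and an unbiased discriminative
    search over degenerate IUPAC consensus motif spaces scored by two-sided
    Fisher exact tests with Bonferroni correction and a Markov background-model
    p-value. A seeded synthetic-data generator produces ground-truthed
    reference catalogs and adapter-bearing FASTQ reads so the whole pipeline
    can be exercised and validated without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
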