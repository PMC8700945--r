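Package: zdosage
Title: Z-Ratio Differential Expression and Gene-Dosage Imbalance for
    Stratified Microarray Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a per-sample Z-score / Z-ratio differential
    expression pipeline for log2 microarray intensity data stratified by
    brain region and age rank, as used in trisomy-21 (Down Syndrome)
    transcriptome studies: per-array standardization, Z-ratio statistics
    with a two-tailed normal test and a 1.96 overexpression rule, a
    log2-fold based gene-dosage ratio (R = 2^M) with copy-number style
    classification, presence filtering of probes, probe-to-gene
    summarization, GEO series-matrix reading and writing, interaction
    network topology summaries, and a seeded synthetic-data generator
    with planted fold changes so that every stage of the analysis is
    testable without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
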