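Package: isocover
Title: Reference-Guided Transcript Assembly via Splice Graphs and Set Cover
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles full-length transcript models from spliced RNA-seq read
    alignments. Exons are inferred per covered region by scoring combinations of
    splice-site-delimited candidate exons with a small linear program over
    subexon coverages; exons are connected into a splice graph whose maximal
    paths are candidate transcripts; the final transcript set is chosen by
    (optionally annotation-weighted) greedy set cover over contiguity
    constraints derived from reads and read pairs. Ships a spliced-read
    simulator with known truth and intron-chain-based accuracy metrics
    (recall, precision, F-value, effective-coverage curves), so the whole
    pipeline is testable end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    boot,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
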