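Package: mycoamp
Title: Processing, Spike-In Calibration and Taxonomy of Variable-Length
    Fungal ITS Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for high-throughput amplicon sequencing
    of variable-length markers such as the fungal rRNA internal transcribed
    spacer (ITS). Implements lossless pre-processing (barcode demultiplexing,
    primer removal with edit-distance tolerance, full-length/padded/truncated
    trimming modes, paired-end merging, expected-error filtering), greedy
    centroid OTU clustering at 97% identity with OTU tables built from
    pre-quality-filter reads, spike-in mock-community calibration of
    tag-switching (index-bleed) with per-OTU table filtering, hybrid
    global-alignment / k-mer bootstrap / least-common-ancestor taxonomy
    assignment, a designer for non-biological synthetic ITS-like spike-in
    communities (SynMock), and a sequencing-run simulator with per-read truth
    so every stage can be validated in a closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
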