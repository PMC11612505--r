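Package: hiddensplit
Title: Copy Number Variant Calling from Short Reads Using Hidden Split Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects deletions and tandem duplications (local copy number
    variants) from paired-end short-read alignments. Besides the classical
    split-read and discordant-pair evidence, the caller exploits hidden split
    reads: unclipped reads whose alignment score would strictly increase if
    they were allowed to split freely into two independently aligned halves,
    the typical signature of full-unit events inside diverged tandem repeats.
    Includes breakpoint consensus piling and junction assembly, insert-size
    statistical testing and depth features, hard and random-forest filtering,
    VCF input/output, repeat-aware callset comparison and clique-cover
    clustering, expected-support (ES) score analysis, and a fully
    self-contained paired-end read simulator for generating truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    ranger,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
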