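Package: msaoutlier
Title: Gap-Based Outlier Detection for Multiple Sequence Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects outlier sequences in multiple sequence alignments from
    the pattern of gaps alone. Pairwise gap distances between aligned
    sequences are computed under a linear, affine or cumulative metric,
    either as a full distance matrix or approximated with a log(N)-seed
    embedding for large alignments. Per-sequence mean distances are
    normalised by bootstrap resampling or by the interquartile range, and
    sequences whose normalised score exceeds a threshold are flagged as
    outliers. Also supports pre-computed Phylip distance matrices and,
    optionally, unaligned protein sequences scored by an external BLAST-
    compatible search tool. Includes a synthetic alignment generator for
    benchmarking detection performance on families with a known gap
    architecture seeded with divergent outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
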