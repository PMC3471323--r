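Package: amplimerge
Title: Probabilistic Assembly of Overlapping Paired-End Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Merges overlapping Illumina forward/reverse amplicon read pairs
    into full-length sequences using per-base quality scores. The overlap
    length is chosen by maximising a likelihood over all candidate offsets;
    mismatched and uncalled bases in the overlap are corrected from the
    higher-quality mate; primers are located probabilistically and stripped;
    each assembly is scored by the geometric mean of its per-base correctness
    probabilities and filtered against user criteria. Includes a synthetic
    read-pair simulator with truth records and an evaluator that classifies
    assemblies by error-correction outcome, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    optparse,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
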