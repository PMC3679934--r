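Package: pyroprofile
Title: Error Profiling for 454 Amplicon Pyrosequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes sequencing errors in 454/pyrosequencing amplicon
    experiments. Provides a synthetic multi-run amplicon read generator with
    homopolymer-length-dependent indel errors, positional quality decay and
    configurable quality miscalibration; primer trimming, semi-global
    read-to-amplicon alignment with homopolymer left-normalization and exon
    clipping; extraction of insertion/deletion/substitution events and their
    partition into true variants, pseudogene side-products and errors against
    a truth set; aggregation into per-type error rates, per-read statistics,
    cross-run reproducibility and positional error distributions; and quality
    score analytics including error-rate-space averaging, homopolymer
    association tests and empirical-versus-estimated quality calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
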