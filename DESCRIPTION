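Package: platmut
Title: Mutagenesis Quantification and Signature Decomposition for
    Platinum-Treated Isogenic Clones
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mutagenic effect of platinum chemotherapeutics
    (cisplatin, carboplatin, oxaliplatin) from whole-genome comparisons of
    isogenic treated and mock-treated cell clones.  Implements unique-mutation
    calling across multiple isogenic samples with a Fisher-type quality score
    and false-positive-calibrated thresholds, 96-channel trinucleotide
    mutation spectra with transcriptional strand bias, de novo non-negative
    matrix factorization of spectra into a direct platinum-related signature
    and an indirect background signature with per-sample exposures, and
    group-level burden and dose-response statistics.  A synthetic-experiment
    generator (reference genome, planted signature mixtures, noisy allele
    counts) makes the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
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
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
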