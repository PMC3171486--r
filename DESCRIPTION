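Package: motifstep
Title: De Novo Discovery of Gapped DNA Motifs by Stepwise Consensus Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers over-represented transcription factor binding motifs,
    gapped or contiguous and up to 20 nt wide, in a foreground sequence set
    (for example ChIP-seq peaks) relative to a background set. The search
    proceeds by stepwise refinement of gapped IUPAC consensuses: exhaustive
    enumeration of two-triplet cores, enrichment filtering by fold change and
    z-score, degeneration into ambiguity codes, extension with informative
    flanking positions, refinement into position weight matrices under a
    maximum a posteriori objective with a third-order Markov background, and
    greedy redundancy removal by PWM correlation. Includes motif-level
    accuracy measures (CompareACE-style similarity, sensitivity and
    specificity) and a seeded synthetic-data generator with planted motifs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    generics,
    ggplot2,
    withr,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
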