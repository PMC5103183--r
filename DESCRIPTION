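Package: tgrspectra
Title: Mutation Calling, Clonal Correction and Spectrum Analysis for
    Transgenic Rodent lacZ Assays Sequenced by NGS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for transgenic rodent (MutaMouse lacZ)
    mutation data sequenced as pooled mutant plaques. Calls mutations from
    duplicate pileups with false-mutation-proportion error correction and a
    plaque-count-derived calling threshold, estimates clonal expansion and
    clonally corrects mutant frequencies, classifies mutations into
    basepair-normalized classes with CpG, homopolymer and dipyrimidine
    context annotation, and compares mutation spectra between treatment
    groups and tissues with Monte Carlo chi-squared and Fisher's exact
    tests. Includes a synthetic plaque-pool simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
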