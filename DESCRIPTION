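Package: epierr
Title: Detection of m6A RNA Modifications from Nanopore Base-Calling Error Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) sites in nanopore direct RNA
    sequencing data from the systematic base-calling "errors" (lowered
    per-base qualities, elevated mismatch and deletion frequencies) that
    modified nucleotides induce. Provides a k-mer-complete synthetic sequence
    designer ("curlcake"-style de Bruijn constructs with minimized
    self-complementary structure), a read simulator with
    modification-dependent error models and partial-methylation mixtures,
    per-site and 5-mer-window feature extraction from alignments, a support
    vector machine classifier over window features with ROC/AUC evaluation,
    and transcriptome-style site calling: RRACH motif scanning, coverage
    filtering, replicate score merging, wild-type versus knockout
    differential calling, and stoichiometry estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    e1071,
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
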