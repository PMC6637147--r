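Package: cpf1screen
Title: Analysis and Design of Multiplexed AsCpf1 (Cas12a) CRISPR Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled CRISPR knockout screens built on the AsCpf1
    (Cas12a) nuclease, whose crRNA self-processing allows several guides for
    one gene to be multiplexed on a single construct. Provides readers and
    validators for guide-library and read-count tables; normalization and
    log2 fold-change computation against reference samples; false-positive-
    rate-controlled active-construct calling against non-essential controls;
    a small-library Bayes-factor essentiality classifier (Low Fat BAGEL) with
    guide-level bootstrap permutations and FDR hit calling; precision-recall
    benchmarking against gold-standard essential/non-essential gene sets,
    including the prevalence null AUC and mAUC/rmAUC temporal separation
    metrics; a position-specific nucleotide preference matrix for AsCpf1
    protospacers fitted from screen fold changes; a TTTV-PAM guide designer
    with homopolymer/BsmBI filters, mismatch-tolerant off-target counting and
    multi-guide crRNA array assembly; and a negative-binomial screen
    simulator for end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
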