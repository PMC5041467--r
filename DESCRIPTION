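Package: famforge
Title: Unsupervised RNA Family Model Construction from a Single Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structural RNA family models fully automatically from a
    single input sequence. Homologs are collected by iterative similarity
    search over an ascending taxonomic traversal; candidates are gated by a
    normalized structure conservation index (nSCI) and dual E-value cutoffs;
    the result is a family of members with a structural alignment, a consensus
    secondary structure and a calibrated family model. Heavyweight external
    tools are abstracted behind backend contracts with in-package reference
    implementations, so the full decision logic runs at desk scale, and a
    synthetic-world simulator (taxonomy, structured RNA family evolved with
    compensatory base-pair mutations, decoy contigs, truth table) supports
    end-to-end evaluation without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
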