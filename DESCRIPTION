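Package: petfloc
Title: Compartment Localization of Plastid Genes and Detection of
    Endosymbiotic Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers whether a chloroplast gene has been transferred to the
    nuclear genome from quantitative PCR evidence, and supports the
    inference with sequence and tree utilities. Implements threshold-cycle
    (Ct) calling and window-of-linearity amplification-efficiency
    estimation on raw fluorescence curves, 2^dCt relative copy numbers
    against dual (nuclear and plastid) single-copy reference genes, and a
    per-strain compartment classifier. Also provides a greedy
    overlap-layout-consensus builder for Sanger reads with best-hit region
    extraction and reading-frame translation, newick tree utilities
    (monophyly, root-to-tip path lengths, alignment column trimming,
    transit-peptide flagging), Dollo-parsimony counting of independent
    plastid-to-nucleus transfer events under irreversible loss, and
    synthetic-data generators for every input so the whole pipeline is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
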