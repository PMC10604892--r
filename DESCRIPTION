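Package: qzfp
Title: Genome-Wide Identification and Characterization of Q-Type C2H2
    Zinc-Finger Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a genome-wide Q-type
    C2H2 zinc-finger protein (ZFP) family analysis workflow: degenerate
    scanning for the CX(2-4)CX(3)FX(3)QALGGHX(3-5)H scaffold and
    classification of proteins into the 1i-4i domain-count groups,
    EAR/L-box motif annotation, sequence-derived physicochemical profiling
    (molecular weight, theoretical pI, instability index, GRAVY),
    neighbor-joining phylogenetics with bootstrap supports and
    anchor-based clade assignment, Nei-Gojobori Ka/Ks estimation with
    selection-class interpretation, strand-aware promoter extraction and
    IUPAC cis-element scanning, and FPKM-based expression profiling with
    tissue-specificity and stress-response calls. Seeded synthetic-data
    generators with machine-readable ground truth make every stage
    testable offline, and a packaged reference table of 35 sugar beet
    family members supports desk-scale reproduction of the family-level
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
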