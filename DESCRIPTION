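Package: hervkit
Title: Locus-Resolved Analysis of HERV-K(HML2) Repeats and Transcripts
Version: 0.1.0
Authors@R: person("Lenz Lab", "Tools", email = "tools@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing human endogenous retrovirus K
    (HERV-K, HML2 subtype) loci and their transcripts: parsing and
    filtering RepeatMasker repeat tables, fragment size accounting,
    solo-LTR versus provirus element classification, orientation-aware
    intersection of loci with gene models, single-nucleotide assignment
    of cDNA clones to near-identical paralogous loci, splice-junction
    inference with canonical/alternative site classification, type I/II
    provirus typing via the 292-bp pol-env segment, delta-Ct qPCR
    quantification of solo-LTR transcript excess, and a fully seeded
    synthetic-genome generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
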