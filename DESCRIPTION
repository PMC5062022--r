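Package: gh1profiler
Title: Detection and Diversity Profiling of Family 1 Glycoside Hydrolase
    Beta-Glucosidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for culture-independent surveys of glycoside
    hydrolase family 1 (GH1) beta-glucosidase diversity. Provides community-level
    physiological profiling of BIOLOG phenotype microplates (blank correction,
    average well-colour development, substrate richness, Shannon diversity,
    per-substrate significance testing and substrate clustering); conserved-motif
    detection in protein alignments and CODEHOP-style degenerate primer design
    with inosine substitution; in-silico PCR with degenerate primers; AluI
    restriction-digest (RFLP) simulation and clone dereplication; six-frame
    translation, local-alignment identity search against a reference panel,
    catalytic-glutamate verification, novelty classification and genus/division
    community tabulation; and neighbor-joining phylogenetics with bootstrap
    support. A synthetic-data generator produces GH1-like protein families, clone
    libraries and plate readings with known ground truth so the whole pipeline is
    testable without environmental samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
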