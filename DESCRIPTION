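Package: hybridELD
Title: Expression-Level Dominance and Nonadditive Expression Analysis for
    Unreplicated Hybrid-Parent Trios
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing an interspecific hybrid's
    transcriptome (and miRNA complement) against its two parents across
    generations, when each library is a single unreplicated pool. Implements
    the Audic-Claverie exact test for two-library count comparisons,
    Benjamini-Hochberg FDR control with a fold-change gate, mid-parent-value
    additivity testing, the twelve-bin expression-level-dominance
    classification, cross-generation inheritance summaries, miRNA-target
    fold-change anticorrelation, hypergeometric term enrichment, and a
    negative-binomial hybrid-trio simulator with planted truth labels for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
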