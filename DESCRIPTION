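Package: miRquiescence
Title: MicroRNA Regulation of Fibroblast Quiescence: Differential
    Expression, Eigengene Projection, Target Calling and Cell-Cycle
    Compositions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a microarray analysis pipeline
    for microRNA regulation in quiescent human fibroblasts.  Provides
    per-feature linear modelling of one-channel microRNA arrays with a
    surrogate-variable covariate and an F-test on the quiescence term;
    singular-value decomposition of an mRNA quiescence timecourse into
    eigengenes with a per-gene proliferation index; bootstrap enrichment
    of predicted microRNA target sets against same-size random gene sets;
    calling of experimentally supported targets from overexpression
    fold-change arrays at a fold-change and FDR cutoff; and a Dirichlet
    maximum-likelihood ratio test for flow-cytometry cell-cycle phase
    compositions.  A synthetic-data module generates every input with
    planted, recoverable structure so each stage can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
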