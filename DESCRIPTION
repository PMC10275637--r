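Package: discoloc
Title: Colocalization and Mechanism Prediction for Discordant GWAS Signals
Version: 0.1.0
Authors@R: person("Analysis", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect genetic loci where two traits share a causal
    variant but with opposite effect directions, such as loci that increase
    abdominal fat accumulation while protecting from type 2 diabetes.
    Implements Wakefield approximate Bayes factor colocalization of GWAS
    summary statistics with hypothesis posteriors (PPH0-PPH4), credible-set
    construction, a sum-of-single-effects fine-mapper on z-scores and LD,
    discordance classification with LD clumping, GWAS-QTL integration by
    approximate-Bayes-factor colocalization and the SMR statistic with
    reconciliation into pleiotropy categories, annotation-enrichment-based
    tissue-of-action scoring, biweight midcorrelation screens, and
    likelihood-ratio tests for dynamic expression. A synthetic-data module
    simulates LD, paired summary statistics under explicit colocalization
    hypotheses, annotation maps with planted enrichment, and expression
    matrices, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
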