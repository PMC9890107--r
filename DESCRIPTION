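Package: seqpsi
Title: Sequential Hybrid Analysis for Forced-Choice Precognition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a preregistered sequential "hybrid" analysis for
    two-alternative forced-choice guessing experiments: an intercept-only
    random-effects logistic regression with a Bonferroni-widened Wald
    confidence interval, and three Bayesian binomial proportion tests with
    beta priors truncated to (0.5, 1) (uniform, knowledge-based and
    replication priors), combined by a conjunction stopping rule at
    pre-specified cumulative-trial analysis points. Also provides the
    conjugate-posterior robustness test (mode, highest density interval and
    region-of-practical-equivalence decision), one-sided exact binomial
    robustness tests, exploratory comparison of observed and chance-level
    success-rate distributions by the earth mover's distance, an odd-even
    split-half reliability check, operating-characteristics simulation of
    the whole sequential design under configurable truth models, and a
    synthetic generator that emulates a born-open trial stream deposited
    in fixed-size batches.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    yaml
Config/testthat/edition: 3
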