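Package: tdeshape
Title: Shape-Constrained Detection of Temporal Expression Patterns in
    Time-Course Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects genes whose expression follows growth, recession, peak,
    or trough dynamics across ordered time points or stages in multi-sample
    single-cell RNA-seq experiments. Each gene is fit with a linear additive
    (mixed) model in which the temporal trend is a nonnegative combination of
    monotone I-spline or convex C-spline basis functions, estimated by a cone
    projection algorithm; per-sample random effects are handled by a
    closed-form block whitening transform. Each shape hypothesis is tested
    against a mixture-of-beta null, the four shape p-values are combined with
    the Cauchy combination rule, and false discovery rates are estimated by
    permuting time labels at the sample level. A gamma-Poisson simulator of
    time-course counts with sample-level batch effects supports calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    splines,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
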