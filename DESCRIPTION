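Package: bhsic
Title: Conditional Independence Testing with Bundled HSIC Statistics and a
    Local Bootstrap
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonparametric conditional independence test for continuous or
    mixed data based on a bundle of local Hilbert-Schmidt Independence
    Criterion (HSIC) statistics. The conditioning variable Z is partitioned
    by k-means, a biased HSIC estimate is computed for (X, Y) within each
    cluster, and the sum of the local estimates is the test statistic. The
    null distribution under X independent of Y given Z is generated by a
    local bootstrap that keeps Z fixed and resamples X and Y independently
    from kernel-weighted nearest-neighbour conditionals, yielding a
    Monte-Carlo p-value. Includes synthetic linear and post-nonlinear data
    generators and a Type-I/Type-II error experiment harness.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, optparse, yaml
Config/testthat/edition: 3
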