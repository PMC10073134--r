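Package: regnonlin
Title: Regulatory Nonlinearity of Boolean Networks via Taylor Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the regulatory nonlinearity of Boolean network
    models of biochemical regulation. Boolean update rules are lifted to
    their multilinear (pseudo-Boolean) extensions by treating inputs as
    independent Bernoulli variables, and each rule is decomposed into a
    finite Taylor series about an unbiased center whose orders separate
    independent from joint (nonlinear) input effects. Networks can be
    simulated exactly or with order-truncated rules, and the resulting
    mean approximation errors are benchmarked against constrained
    (wiring- and bias-preserving) and unconstrained random ensembles to
    yield percentage-change and approximability scores. Includes a
    BoolNet-style '.bnet' rule reader/writer, a seeded random network
    generator, per-order nonlinearity spectra, and category-level
    comparisons via Welch's t-test and the F-test of equal variances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
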