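Package: hytest
Title: Exact Combinatorial Differential Expression Test for Paired Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Hy-test, an exact test of differential gene
    expression for paired two-condition designs (e.g. tumour vs matched
    normal tissue). Expression profiles are discretized into down-, no-change
    and up-regulated signs by a per-gene two-threshold cut chosen to maximize
    the number of discordant pairs, and the discordance count is referred to
    an exact null distribution obtained from a convolution of multivariate
    hypergeometric distributions over random tissue labellings and pairings.
    Includes the accompanying preprocessing steps (duplicate collapsing,
    quantile normalization, log2 transform), an empirical-Bayes moderated
    paired t-test comparator, a Monte Carlo power study with log-normal and
    power-law marginals coupled by a Gaussian copula, and hypergeometric
    association and gene-set over-representation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
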