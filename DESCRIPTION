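Package: divbattery
Title: Diversification-Rate Slowdown Tests for Ultrametric Chronograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A battery of diversification-dynamics analyses for rooted,
    binary, ultrametric chronograms: the gamma statistic and its asymptotic
    constancy test, the Monte Carlo constant-rates (MCCR) correction for
    incompletely sampled clades, maximum-likelihood fitting of rate-constant
    (Yule, birth-death) and rate-variable (two-rate Yule, linear and
    exponential diversity-dependent, and time-varying SPVAR/EXVAR/BOTHVAR)
    models with AIC model selection, parametric-bootstrap p-values for the
    rate-constant versus rate-variable contrast, lineage-through-time
    curves, and forward simulators for all of the above that generate the
    test inputs synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats, utils
Suggests: testthat (>= 3.0.0), withr, phytools, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
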