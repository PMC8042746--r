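Package: phyloconv
Title: Convergence Diagnostics for Bayesian Phylogenetic MCMC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-chain and multi-chain convergence assessment for
    Bayesian phylogenetic MCMC output. Reads MrBayes-style parameter
    (.p) and tree (.t) sample files, applies burn-in and thinning, and
    computes effective sample sizes and autocorrelation times, the
    Gelman-Rubin potential scale reduction factor, the average standard
    deviation of split frequencies, split-frequency correlations among
    chains, and topological effective sample sizes based on tree
    distances. Provides threshold classification with failure binning,
    diagnostic-congruence tables, Metropolis-coupling heating
    recommendations, before/after re-analysis comparison, and
    corpus-level survey statistics (parameter correlation matrices,
    principal component analysis, multiple regression). A synthetic
    posterior generator with analytically known convergence properties
    supports calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
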