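Package: CastorClock
Title: Bayesian Relaxed-Clock Dating and Substitution-Rate Comparison for
    Mitogenome-Scale Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-topology Bayesian divergence dating under an uncorrelated
    lognormal relaxed molecular clock with a pure-birth (Yule) node-age prior
    and zero-truncated normal fossil calibrations, together with the
    downstream substitution-rate analyses that motivate such datings:
    extraction of tip and path-averaged branch rates, Mann-Whitney/Wilcoxon
    rank-sum comparisons between clades, and ordinary least-squares
    regressions of rates on life-history traits (maximum lifespan, body mass,
    age at sexual maturity). Includes a GTR+I+Gamma likelihood engine
    (Felsenstein pruning, eigendecomposition of the reversible generator), a
    seeded synthetic-data generator (Yule trees, lognormal branch rates,
    sequence simulation, trait simulation) so the whole pipeline is testable
    without external sequence downloads, MCMC trace utilities (burn-in
    removal and combining, effective sample size, highest posterior density
    intervals), and a small pipeline driver with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'alignment.R'
    'timetree.R'
    'trace.R'
    'substmodel.R'
    'mcmc.R'
    'ratestats.R'
    'simulate.R'
    'pipeline.R'
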