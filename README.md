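# CastorClock

Bayesian relaxed-clock divergence dating on a fixed topology, and the
substitution-rate comparisons that follow from it — built for the kind of
question raised by slow-evolving, long-lived lineages such as beavers
(*Castor*) inside an otherwise fast-evolving rodent phylogeny: *when did
this clade diverge, how much slower is its mitochondrial clock, and does
that slowness track life history?*

## What it implements

**Dating.** Fixed-topology Metropolis–Hastings sampling of internal node
ages, per-branch substitution rates and clock hyperparameters under:

- a GTR+I+Γ pruning likelihood (Felsenstein's algorithm over a discrete
  invariant+gamma site-rate mixture, ambiguity codes as partial
  observations, per-node log-scaling; compiled engine with a pure-R
  reference implementation held to it by tests);
- an uncorrelated lognormal relaxed clock: branch rates iid lognormal with
  arithmetic mean μ and log-sd σ;
- a pure-birth (Yule) node-age prior conditioned on the root age, with
  zero-truncated normal fossil calibrations on MRCA ages (the root must be
  calibrated — see the methods vignette for why that makes the calibrated
  root's prior marginal exact);
- trace utilities: per-trace burn-in removal and combining, effective
  sample size, shortest-interval HPDs, clade-age summaries
  (mean/median/95% HPD) and posterior-mean annotation of the topology.

**Rate comparison.** From a rate-annotated time tree: tip rates,
path-averaged rates (arithmetic mean from the ancestral node connecting
the tested taxa down to each tip), Mann–Whitney U / Wilcoxon rank-sum
tests (enumeration-exact or continuity-corrected normal, `U = #{x>y} +
½·ties`), group collapsing to a single mean point, and OLS regressions of
rates on life-history traits (maximum lifespan, body mass, age at sexual
maturity) with pairwise deletion of missing values.

**Synthetic data.** Seeded generators for forward Yule trees, lognormal
branch rates with an optional slow clade, sequence evolution along the
tree, linear rate–trait relationships, and a 24-taxon "beaver-like"
bundle (6-tip slow clade at half the mean rate, 2 kb alignment, lifespans
declining with rate) so every downstream stage is testable offline.

**Pipeline.** `runPipeline()` ties the stages together (`simulate`,
`date`, `summarize`, `ratetest`, `regress`) with YAML configuration,
per-stage provenance JSON and TSV/FASTA/Newick artifacts;
`inst/scripts/castorclock.R` is a thin shell wrapper.

## Worked example

```r
library(CastorClock)

fx <- beaverLikeFixture(seed = 1)          # 24 taxa, 6-tip slow clade
cal <- list(calibrationPrior("root", mean = rootAge(fx$tree), sd = 10))
cfg <- mcmcConfig(chainLength = 50000, logEvery = 50, seed = 1)
trace <- runMCMC(fx$alignment, fx$tree, substitutionModel(), cal, cfg)
post <- combineTraces(list(trace), burninFraction = 0.10)

summarizeCladeAge(post, "root", fx$tree)
#> $mean
#> [1] 65.58432
#> $median
#> [1] 65.59054
#> $hpd
#> [1] 47.45863 84.20761
#> $n
#> [1] 900

annotated <- annotatePosteriorRates(post, fx$tree)
rep <- rateComparisonReport(annotated, fx$cladeLabels$slow_clade,
                            fx$cladeLabels[c("mouse_clade", "all_taxa")],
                            traits = fx$traits)
rep$tests
#>    comparison rate_type  U      p_value               method n_focal n_rest
#> 1 mouse_clade       tip 10 0.0037316266 normal-approximation       6     18
#> 2 mouse_clade  averaged  0 0.0003615509 normal-approximation       6     18
#> 3    all_taxa       tip 10 0.0037316266 normal-approximation       6     18
#> 4    all_taxa  averaged  0 0.0003615509 normal-approximation       6     18
rep$regressions
#>      trait rate_type         slope  intercept r_squared     p_value  n
#> 1 lifespan       tip -0.0007212286 0.02897231 0.3687230 0.005828983 19
#> 2 lifespan  averaged -0.0001931764 0.02178955 0.2716401 0.022118912 19
```

Reading it: the simulation's true root age for this seed is 66.5 my and
the posterior mean is 65.6 my with the truth inside the 95% HPD. The slow
clade's posterior tip rates sit almost entirely below the rest (U = 10 of
a possible 6×18 = 108; U = 0 for averaged rates is complete separation),
significant at p ≈ 0.004 and 0.0004. With the six slow-clade taxa
collapsed to one point, lifespan explains ~37% (tip) and ~27% (averaged)
of the rate variance across 19 points, with the expected negative slopes.
(For this seed the smallest ancestral clade holding at least half the taxa
is the root, so the "mouse-clade" and all-taxa comparisons coincide;
numbers vary with seed and chain settings — these are the values this
example printed.)

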