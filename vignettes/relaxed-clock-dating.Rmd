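---
title: "Relaxed-clock divergence dating and substitution-rate comparison with CastorClock"
author: "CastorClock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxed-clock divergence dating and substitution-rate comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CastorClock)
```

## The problem this package addresses

Mitogenome-scale alignments of rodents (and other mammals) show strong
among-lineage variation in substitution rate: long-lived, large-bodied
lineages such as beavers accumulate mitochondrial substitutions much more
slowly than mice or voles. Two analyses hang off that observation:

1. **Divergence dating.** With rates varying across branches, node ages can
   only be estimated under a *relaxed* molecular clock, with external
   (fossil) calibrations pinning the time scale.
2. **Rate comparison.** Once per-branch rates have been estimated, one can
   ask whether a focal clade's rates differ from the rest (rank-sum tests)
   and whether rates covary with life-history traits such as maximum
   lifespan (linear regressions).

CastorClock implements both halves on a *fixed* rooted topology, plus a
seeded synthetic-data generator so that the whole pipeline can be exercised
and validated without any sequence downloads.

## The model

### Substitution process

Sites evolve under GTR+I+&Gamma;: a general time-reversible 4-state chain
with stationary frequencies $\pi$, exchangeabilities
$(s_{AC},\dots,s_{GT})$, a proportion $p_{inv}$ of invariant sites and
gamma-distributed rate variation (shape $\alpha$, $k$ equal-probability
categories represented by their category means). The generator is scaled so
that the stationary substitution rate is one, and the site-rate mixture
(invariant class at rate 0 plus the rescaled gamma classes) has mean one.
With both normalizations, a branch's `rate × duration` is its expected
number of substitutions per site, which keeps rates in
substitutions/site/my and ages in my interpretable.

The default `substitutionModel()` uses $p_{inv} = 0.2559$ and
$\alpha = 0.4721$ with four categories — the model-fit values of the
mitogenome data set this package's fixtures emulate. The exchangeabilities
and base frequencies of that fit were never published, so the defaults for
those two blocks are **synthetic** (a transition-biased, G-poor choice that
mimics vertebrate mtDNA) and should be replaced by your own estimates for
real analyses.

The likelihood is the Felsenstein pruning algorithm over the site-rate
mixture, with IUPAC ambiguity codes as partial observations (each
compatible base gets conditional likelihood one) and gaps/`?` fully
missing. Partials are log-scaled per node, so 16 kb alignments do not
underflow. Two implementations exist on purpose: a pure-R reference
(`logLikelihood()`) and a compiled engine inside the sampler; the test
suite holds them to each other to $10^{-8}$ at logged MCMC states, and both
to a brute-force state-enumeration oracle on small trees.

### Priors

The sampled state is: internal node ages, one rate per branch, the clock
hyperparameters $\mu$ (mean rate) and $\sigma$ (log-sd), and the birth rate
$\lambda$.

* **Branch rates** are iid lognormal with arithmetic mean $\mu$ and log-sd
  $\sigma$ (location $\log\mu - \sigma^2/2$) — the "uncorrelated lognormal"
  relaxed clock, kept continuous rather than discretized into rate
  categories.
* **Node ages** follow the pure-birth (Yule) process *conditioned on the
  root age*: the $n-2$ non-root internal ages are iid
  truncated-exponential with rate $\lambda$ on $[0, T_{root}]$, restricted
  to orderings compatible with the topology. Because order compatibility is
  a rank event, its probability does not depend on $\lambda$ or $T_{root}$;
  the practical consequence is that the prior marginal of a root-calibrated
  age is *exactly* its calibration density. That turns the package's
  prior-sampling equivalence test into an exact check instead of an
  approximate one, and it is why `runMCMC()` requires a calibration on the
  root: without one, the conditioned form leaves the time scale without a
  proper prior. Additional internal-node calibrations simply multiply in.
* **Calibrations** are normal densities on MRCA ages, truncated at zero and
  renormalized by default (negative ages are meaningless). The study this
  package emulates used six such fossil calibrations, whose exact values
  were published only in supplementary material; calibrations are therefore
  always user-supplied configuration, never package defaults.
* **Hyperpriors** (the underlying study is silent, so these are package
  choices, deliberately broad): $\mu \sim$ lognormal(median 0.01
  subs/site/my, log-sd 1.5), $\sigma \sim$ Exponential(mean 0.5),
  $\lambda \sim$ lognormal(median 0.1/my, log-sd 1.5).

$\sigma = 0$ is refused as degenerate: a strict clock is something you
simulate (`assignBranchRates(..., clockSigma = 0)`), not something this
sampler can sit on.

### The sampler

`runMCMC()` is plain Metropolis–Hastings with one elementary proposal per
generation:

| move | what it does | Hastings term |
|---|---|---|
| `rootScale` | multiplies the root age by $e^{u}$ | $\log s$ |
| `nodeSlide` | uniform draw between oldest child and parent | 0 |
| `rateScale` | multiplies one branch rate | $\log s$ |
| `muScale`, `sigmaScale`, `lambdaScale` | scalar scale moves | $\log s$ |
| `muRateScale` | scales $\mu$ and *all* rates together | $(n_E+1)\log s$ |
| `upDown` | ages $\times s$, rates and $\mu$ $\div s$ | $(n_{int}-n_E-1)\log s$ |
| `rateSpreadScale` | scales $\sigma$ and the log-rate spread | $n_E \log s$ |

The three joint moves matter: $\mu$ and the branch rates are strongly
coupled (as are ages and rates through the expected-substitution
confounding), and single-parameter moves alone mix the hyperparameters far
too slowly. `upDown` leaves every branch's expected substitutions — hence
the likelihood — exactly unchanged, so it is evaluated against the prior
only. Node-age bounds are enforced by the proposals, so the age-ordering
invariant holds after every accepted move; acceptance rates per move are
reported on the returned trace and a tuning warning is emitted outside
(0.05, 0.95).

The chain is logged every `logEvery` generations including generation 0,
with columns for the posterior/likelihood/prior, $\mu$, $\sigma$,
$\lambda$, every internal node age (`age_<node>`) and every branch rate
(`rate_<childNode>`), which is exactly what the downstream trace utilities
(`combineTraces()`, `effectiveSampleSize()`, `hpdInterval()`,
`summarizeCladeAge()`, `annotatePosteriorRates()`) consume. Burn-in is
removed per input trace *before* concatenation, mirroring the manual
log-combining workflow this reproduces.

## The synthetic-data generator

`beaverLikeFixture()` emulates the statistical structure of the study
design this package was built around: 24 taxa on a Yule tree, a 6-tip slow
clade standing in for the six beaver mitogenomes, lognormal branch rates,
GTR+I+&Gamma; sequences, and lifespans that decline with tip rate. Its
defaults are the package's study conditions, chosen once:

* `birthRate = 0.04`/my: the expected height of a 24-tip forward Yule tree
  is $(H_{24}-1)/\lambda \approx 67$ my — the rodent-MRCA time scale.
* `clockMean = 0.02` subs/site/my: a typical rodent mitochondrial rate.
* `clockSigma = 0.4`: moderate among-branch heterogeneity of the size
  relaxed-clock fits report for mammal mtDNA; small enough that a halved
  clade mean (`slowMultiplier = 0.5`) produces the near-complete separation
  of slow-clade and background rates that motivates the rank-sum analysis.
* lifespans: `27 - 1000 × rate` years plus N(0, 4) noise, floored at 0.1 —
  about 17 y at the slow-clade rate and 7 y at the background rate, a
  rodent-like spread with a clearly negative rate–lifespan slope.
* The Yule draw is conditioned on containing a clade of exactly 6 tips by
  deterministic seed-derived rejection resampling; the bundle is a pure
  function of its seed.

The 12-taxon recovery fixture used by the tests rescales a Yule tree to a
10 my root, uses a nearly strict clock (`clockSigma = 0.05`) and a root
calibration N(10, 2) — small enough that twenty replicates of a
60,000-generation chain on a 1.2 kb alignment run in a few minutes, which
is the problem size the validation suite and the acceptance script use
throughout (the engine is built for correctness at these scales, not for
50M-generation production runs).

What the generator deliberately does **not** emulate: indels and alignment
error (simulated alignments are gap-free), base-composition drift across
lineages, among-gene partitioning, extinction (pure birth only), and
phylogenetic correlation of life-history traits (traits depend on rates
only through the linear model). Passing tests therefore certify the
machinery — likelihood, sampler, statistics — on data that satisfy the
model's assumptions; they do not certify that real mitogenome data satisfy
them.

## The rate-comparison statistics

* **Tip rates** are the terminal-branch rates; **path-averaged rates** are
  the unweighted arithmetic mean of the branch rates on the path from the
  ancestral node connecting the tested taxa down to and including the
  terminal branch. The path excludes the branch above that ancestor — the
  reading of "branches leading to the ancestral node" we judged most
  plausible — with `includeStem = TRUE` available for sensitivity analysis,
  and a duration-weighted variant behind `timeWeighted = TRUE`.
* **`rankSumTest()`** counts $U = \#\{x_i > y_j\} + \tfrac12\#\text{ties}$.
  Exact mode enumerates all $\binom{n_1+n_2}{n_1}$ labelings (tie-free
  only) and doubles the smaller tail; normal mode applies the mid-rank tie
  correction and a 0.5 continuity correction, matching
  `wilcox.test(correct = TRUE)` — the convention required to reproduce the
  published U/p pairs this analysis style reports. `auto` uses exact for
  tie-free samples with $n_1 + n_2 \le 20$.
* **`collapseGroup()`** replaces a group (e.g. six conspecific beavers) by
  its arithmetic-mean point before regression, avoiding pseudo-replication;
  missing trait values are excluded per column, so a trait missing for all
  group members stays missing.
* **`linearRegression()`** is ordinary least squares on untransformed
  values (the analysis this reproduces states plain linear regressions); a
  `logY` flag exists because the comparative literature often logs rates,
  but it is never applied silently. Missing pairs are dropped pairwise.

Phylogenetically independent contrasts/PGLS and multiple-testing correction
are deliberately out of scope: the reproduced analysis used neither.

## Numerical choices and edge cases

* Matrix exponentials via eigendecomposition of the symmetrized reversible
  generator; tiny negative entries from rounding are clamped at zero.
* Site patterns are compressed before pruning; per-node, per-pattern
  log-scaling guards against underflow.
* `hpdInterval()` returns the first (lowest) of tied shortest windows;
  `effectiveSampleSize()` sums empirical autocorrelations until the first
  non-positive one and caps at $n$; a constant series is a diagnostic
  error, not ESS $= n$.
* Zero-duration branches and zero-length alignments are legal degenerate
  inputs (identity transition matrices, log-likelihood 0 respectively);
  ragged alignments, duplicate taxa, polytomies, negative branch lengths
  and age-ordering violations are hard errors.
* Column intervals for `removeColumns()` are 1-based inclusive, the NEXUS
  convention; the excluded control-region block of the emulated study is
  user input because its exact coordinates were never published.
* Chain initialization rescales the starting tree to the root-calibration
  mean and seeds all rates with a crude Jukes–Cantor distance/time guess,
  which shortens burn-in at the tested chain lengths.

## Worked example

```{r example, eval = FALSE}
fx <- beaverLikeFixture(seed = 1)
cal <- list(calibrationPrior("root", mean = rootAge(fx$tree), sd = 10))
cfg <- mcmcConfig(chainLength = 50000, logEvery = 50, seed = 1)
trace <- runMCMC(fx$alignment, fx$tree, substitutionModel(), cal, cfg)
post <- combineTraces(list(trace), burninFraction = 0.10)
summarizeCladeAge(post, "root", fx$tree)
annotated <- annotatePosteriorRates(post, fx$tree)
rateComparisonReport(annotated, fx$cladeLabels$slow_clade,
                     fx$cladeLabels[c("mouse_clade", "all_taxa")],
                     traits = fx$traits)
```

The same flow is scriptable end-to-end through `runPipeline()` (stages
`simulate`, `date`, `summarize`, `ratetest`, `regress`) with a YAML
configuration and per-stage provenance JSON, or from a shell via
`inst/scripts/castorclock.R`.

## Known limitations

* Fixed topology only; no topology sampling, no tip dating, no marginal
  likelihoods.
* Substitution-model parameters are fixed during MCMC (supplied as
  configuration), not sampled.
* The root must carry a calibration (see the prior construction above).
* Continuous lognormal branch rates; whether a discretized-rate
  implementation of the same clock differs materially is noted but not
  resolved here.
* The worked examples that compare against the emulated study's published
  per-taxon rate and trait tables require those supplementary tables,
  which are not redistributed with the package; the corresponding checks
  fail (by design, loudly) until the user supplies the files under
  `inst/extdata/supplementary/`.
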