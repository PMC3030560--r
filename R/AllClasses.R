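#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib CastorClock, .registration = TRUE
NULL

## Valid alignment states: nucleotides, IUPAC ambiguities, gap/missing.
.VALID_STATES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-", "?")

#' Multiple sequence alignment of nucleotide states
#'
#' A taxa-by-columns character matrix over `{A,C,G,T}`, IUPAC ambiguity codes
#' and the gap/missing symbols `-` and `?`. Row names are the (unique) taxon
#' labels; all rows have equal length. Build one with [alignment()] or read
#' one from disk with [readAlignment()].
#'
#' @slot mat Character matrix of single-character states, rows named by taxon.
#' @seealso [readAlignment()], [removeColumns()], [simulateAlignment()]
#' @export
setClass("Alignment", representation(mat = "matrix"))

setValidity("Alignment", function(object) {
  m <- object@mat
  if (!is.character(m)) return("alignment matrix must be character")
  if (nrow(m) > 0 && is.null(rownames(m))) return("rows must be named by taxon")
  if (anyDuplicated(rownames(m))) return("duplicate taxon labels")
  bad <- setdiff(unique(as.vector(m)), .VALID_STATES)
  if (length(bad) > 0)
    return(paste0("invalid alignment states: ", paste(bad, collapse = ", ")))
  TRUE
})

#' Rooted time tree with node ages and optional branch rates
#'
#' Wraps an `ape::phylo` topology. Node ages (millions of years, tips at 0
#' unless dated) are authoritative; branch durations are always derived as
#' parent age minus child age, never stored independently. Branches may carry
#' a substitution rate (substitutions/site/my) and arbitrary further
#' annotations, which round-trip through the annotated-Newick reader/writer.
#'
#' @slot phylo A rooted binary `phylo` object (topology only; edge lengths
#'   are kept in sync with the ages).
#' @slot ages Numeric vector of node ages indexed by ape node number
#'   (tips `1..n`, then internal nodes).
#' @slot rates Numeric vector of per-branch rates aligned with the rows of
#'   `phylo$edge`; `NA` marks an unannotated branch.
#' @slot annotations List (one element per edge) of named character vectors
#'   holding any further `[&key=value]` branch annotations verbatim.
#' @seealso [timeTree()], [readTimeTree()], [writeTimeTree()],
#'   [assignBranchRates()]
#' @export
setClass("TimeTree",
         representation(phylo = "ANY", ages = "numeric", rates = "numeric",
                        annotations = "list"))

setValidity("TimeTree", function(object) {
  phy <- object@phylo
  if (!inherits(phy, "phylo")) return("phylo slot must be an ape phylo object")
  if (!ape::is.rooted(phy)) return("tree must be rooted")
  if (!ape::is.binary(phy)) return("tree must be binary (no polytomies)")
  nn <- ape::Ntip(phy) + phy$Nnode
  if (length(object@ages) != nn) return("ages must have one entry per node")
  if (any(!is.finite(object@ages)) || any(object@ages < 0))
    return("node ages must be finite and non-negative")
  dur <- object@ages[phy$edge[, 1]] - object@ages[phy$edge[, 2]]
  if (any(dur < -1e-9))
    return("child node older than its parent (age ordering violated)")
  if (length(object@rates) != nrow(phy$edge))
    return("rates must have one entry per edge")
  r <- object@rates[!is.na(object@rates)]
  if (any(r <= 0)) return("branch rates must be positive where present")
  if (length(object@annotations) != nrow(phy$edge))
    return("annotations must have one entry per edge")
  TRUE
})

#' GTR+I+Gamma substitution model
#'
#' General time-reversible nucleotide model with a proportion of invariant
#' sites and discrete-gamma rate variation across sites. The generator built
#' from it ([buildRateMatrix()]) is scaled to one expected substitution per
#' unit time at stationarity, and the site-rate mixture
#' ([siteRateMixture()]) has mean one, so `rate x duration` on a branch is
#' expected substitutions per site.
#'
#' @slot exchangeabilities Six positive relative rates in the order
#'   AC, AG, AT, CG, CT, GT.
#' @slot baseFrequencies Four positive stationary frequencies (A, C, G, T)
#'   summing to one.
#' @slot pInvariant Proportion of invariant sites in `[0, 1)`.
#' @slot gammaShape Shape of the gamma distribution of site rates (> 0).
#' @slot nCategories Number of discrete gamma categories (>= 1).
#' @seealso [substitutionModel()], [logLikelihood()]
#' @export
setClass("SubstitutionModel",
         representation(exchangeabilities = "numeric",
                        baseFrequencies = "numeric",
                        pInvariant = "numeric",
                        gammaShape = "numeric",
                        nCategories = "integer"))

setValidity("SubstitutionModel", function(object) {
  if (length(object@exchangeabilities) != 6 ||
      any(!is.finite(object@exchangeabilities)) ||
      any(object@exchangeabilities <= 0))
    return("exchangeabilities must be 6 positive numbers (AC,AG,AT,CG,CT,GT)")
  f <- object@baseFrequencies
  if (length(f) != 4 || any(!is.finite(f)) || any(f <= 0))
    return("baseFrequencies must be 4 positive numbers")
  if (abs(sum(f) - 1) > 1e-12) return("baseFrequencies must sum to 1")
  if (length(object@pInvariant) != 1 || object@pInvariant < 0 ||
      object@pInvariant >= 1)
    return("pInvariant must lie in [0, 1)")
  if (length(object@gammaShape) != 1 || object@gammaShape <= 0)
    return("gammaShape must be > 0")
  if (length(object@nCategories) != 1 || object@nCategories < 1L)
    return("nCategories must be >= 1")
  TRUE
})

#' Discrete site-rate mixture (invariant class plus gamma categories)
#'
#' @slot rates Non-negative category rates; the zero-rate class is the
#'   invariant-sites class.
#' @slot weights Category probabilities summing to one. The mixture always
#'   has mean one: `sum(weights * rates) == 1`.
#' @seealso [siteRateMixture()]
#' @export
setClass("SiteRateMixture",
         representation(rates = "numeric", weights = "numeric"))

setValidity("SiteRateMixture", function(object) {
  if (length(object@rates) != length(object@weights))
    return("rates and weights must have equal length")
  if (any(object@rates < 0)) return("category rates must be non-negative")
  if (any(object@weights < 0)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (abs(sum(object@weights * object@rates) - 1) > 1e-9)
    return("mixture must have mean rate 1")
  TRUE
})

#' Fossil calibration prior on a clade's MRCA age
#'
#' A normal density on the age (my) of the most recent common ancestor of
#' `clade`, optionally truncated at zero and renormalized (negative ages are
#' meaningless).
#'
#' @slot clade Character vector of at least two taxon labels whose MRCA is
#'   calibrated, or the special label `"root"` for the root node.
#' @slot mean Prior mean age in my.
#' @slot sd Prior standard deviation in my (> 0).
#' @slot truncateAtZero Truncate (and renormalize) the normal at age 0.
#' @seealso [calibrationPrior()], [runMCMC()]
#' @export
setClass("CalibrationPrior",
         representation(clade = "character", mean = "numeric", sd = "numeric",
                        truncateAtZero = "logical"))

setValidity("CalibrationPrior", function(object) {
  if (length(object@clade) < 1) return("clade must name taxa (or 'root')")
  if (length(object@clade) == 1 && !identical(object@clade, "root"))
    return("a calibrated clade needs >= 2 taxa (or the label 'root')")
  if (object@sd <= 0) return("calibration sd must be > 0")
  if (!is.finite(object@mean)) return("calibration mean must be finite")
  TRUE
})

#' MCMC run configuration
#'
#' @slot chainLength Number of generations (one elementary proposal each).
#' @slot logEvery Logging interval in generations; generation 0 is logged.
#' @slot burninFraction Fraction of each trace discarded by
#'   [combineTraces()]; default 0.10.
#' @slot seed Integer seed for the run.
#' @slot moveWeights Named relative weights for the proposal types
#'   `rootScale`, `nodeSlide`, `rateScale`, `muScale`, `sigmaScale`,
#'   `lambdaScale`.
#' @slot tuning Named proposal window sizes (log-scale half-widths) for the
#'   scale moves.
#' @seealso [mcmcConfig()], [runMCMC()]
#' @export
setClass("MCMCConfig",
         representation(chainLength = "numeric", logEvery = "numeric",
                        burninFraction = "numeric", seed = "integer",
                        moveWeights = "numeric", tuning = "numeric"))

setValidity("MCMCConfig", function(object) {
  if (object@chainLength < 1) return("chainLength must be >= 1")
  if (object@logEvery < 1) return("logEvery must be >= 1")
  if (object@chainLength < object@logEvery)
    return("chainLength must be >= logEvery")
  if (object@burninFraction < 0 || object@burninFraction >= 1)
    return("burninFraction must lie in [0, 1)")
  if (any(object@moveWeights < 0) || sum(object@moveWeights) <= 0)
    return("moveWeights must be non-negative with positive sum")
  TRUE
})

#' MCMC trace: sampled scalars, one row per logged generation
#'
#' Columns always include `generation`, `posterior`, `likelihood`, `prior`,
#' the clock hyperparameters `mu` (mean branch rate), `sigma` (log-sd of
#' branch rates) and the birth rate `lambda`, plus one `age_<node>` column
#' per internal node and one `rate_<childNode>` column per branch.
#'
#' @slot samples Data frame of logged values, `generation` strictly
#'   increasing.
#' @slot logEvery Logging interval of the run (generations).
#' @slot acceptance Named acceptance rates per move type (may be empty for
#'   combined traces).
#' @seealso [runMCMC()], [combineTraces()], [summarizeCladeAge()]
#' @export
setClass("ClockTrace",
         representation(samples = "data.frame", logEvery = "numeric",
                        acceptance = "numeric"))

setValidity("ClockTrace", function(object) {
  s <- object@samples
  if (nrow(s) == 0) return("trace must contain at least one sample")
  if (!"generation" %in% names(s)) return("trace must have a generation column")
  g <- s$generation
  if (any(diff(g) <= 0)) return("generation must be strictly increasing")
  TRUE
})

#' Rank-sum (Mann-Whitney U) test result
#'
#' @slot U The U statistic, counting pairs where the first sample exceeds the
#'   second (ties count one half).
#' @slot pValue Two-sided p-value.
#' @slot method `"exact"` (full labeling enumeration) or
#'   `"normal-approximation"` (mid-rank tie correction plus 0.5 continuity
#'   correction).
#' @slot n1,n2 Group sizes.
#' @seealso [rankSumTest()]
#' @export
setClass("RankSumResult",
         representation(U = "numeric", pValue = "numeric", method = "character",
                        n1 = "integer", n2 = "integer"))

setValidity("RankSumResult", function(object) {
  if (object@U < 0 || object@U > object@n1 * object@n2)
    return("U must lie in [0, n1*n2]")
  if (object@pValue < 0 || object@pValue > 1) return("p must lie in [0, 1]")
  TRUE
})

#' Ordinary least-squares regression result
#'
#' @slot slope,intercept Fitted coefficients.
#' @slot rSquared Coefficient of determination in `[0, 1]`.
#' @slot pValue Two-sided t-test p-value on the slope (n - 2 df).
#' @slot n Number of complete pairs used.
#' @seealso [linearRegression()]
#' @export
setClass("RegressionResult",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", pValue = "numeric",
                        n = "integer"))

setValidity("RegressionResult", function(object) {
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    return("rSquared must lie in [0, 1]")
  if (object@n < 3) return("regression needs n >= 3")
  TRUE
})
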