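#' @include AllClasses.R AllGenerics.R timetree.R substmodel.R trace.R
NULL

## Hyperprior constants shared by the R prior and the compiled engine:
## mean clock rate mu ~ lognormal(median 0.01 subs/site/my, broad),
## rate log-sd sigma ~ exponential(mean 0.5),
## birth rate lambda ~ lognormal(median 0.1/my, broad).
.HYPER <- c(muMeanlog = log(0.01), muSdlog = 1.5,
            sigmaRate = 2, lambdaMeanlog = log(0.1), lambdaSdlog = 1.5)

#' Construct a fossil calibration prior
#'
#' @param clade Character vector of >= 2 taxon labels whose MRCA age is
#'   calibrated, or `"root"`.
#' @param mean,sd Normal prior mean and standard deviation in my.
#' @param truncateAtZero Truncate the normal at age 0 and renormalize
#'   (default `TRUE`; negative ages are meaningless).
#' @return A [CalibrationPrior-class].
#' @examples
#' calibrationPrior("root", mean = 10, sd = 2)
#' @export
calibrationPrior <- function(clade, mean, sd, truncateAtZero = TRUE) {
  new("CalibrationPrior", clade = as.character(clade), mean = as.numeric(mean),
      sd = as.numeric(sd), truncateAtZero = isTRUE(truncateAtZero))
}

setMethod("show", "CalibrationPrior", function(object) {
  cat("Calibration: MRCA(",
      paste(utils::head(object@clade, 4), collapse = ","),
      if (length(object@clade) > 4) ",..." else "",
      ") ~ N(", object@mean, ", ", object@sd, ")",
      if (object@truncateAtZero) " truncated at 0" else "", "\n", sep = "")
})

#' Construct an MCMC configuration
#'
#' @param chainLength Number of generations.
#' @param logEvery Logging interval (generations); generation 0 is logged.
#' @param burninFraction Default burn-in fraction for [combineTraces()].
#' @param seed Integer seed.
#' @param moveWeights Named relative proposal weights; defaults weight the
#'   node-age and branch-rate moves roughly by their dimension.
#' @param tuning Named log-scale half-widths of the scale proposals.
#' @return An [MCMCConfig-class].
#' @export
mcmcConfig <- function(chainLength, logEvery = max(1, chainLength %/% 1000),
                       burninFraction = 0.10, seed = 1L,
                       moveWeights = c(rootScale = 3, nodeSlide = 10,
                                       rateScale = 12, muScale = 3,
                                       sigmaScale = 3, lambdaScale = 2,
                                       muRateScale = 3, upDown = 4,
                                       rateSpreadScale = 2),
                       tuning = c(rootScale = 0.2, rateScale = 0.8,
                                  muScale = 0.5, sigmaScale = 0.6,
                                  lambdaScale = 0.8, muRateScale = 1.0,
                                  upDown = 0.4, rateSpreadScale = 0.5)) {
  if (chainLength < 1) stop("chainLength must be >= 1")
  defW <- eval(formals(mcmcConfig)$moveWeights)
  defT <- eval(formals(mcmcConfig)$tuning)
  if (!is.null(names(moveWeights))) {
    unknown <- setdiff(names(moveWeights), names(defW))
    if (length(unknown) > 0)
      stop("unknown move type(s): ", paste(unknown, collapse = ", "))
    defW[names(moveWeights)] <- moveWeights
    moveWeights <- defW
  } else if (length(moveWeights) != length(defW))
    stop("moveWeights must be named or give all ", length(defW), " weights")
  if (!is.null(names(tuning))) {
    unknown <- setdiff(names(tuning), names(defT))
    if (length(unknown) > 0)
      stop("unknown tuning parameter(s): ", paste(unknown, collapse = ", "))
    defT[names(tuning)] <- tuning
    tuning <- defT
  } else if (length(tuning) != length(defT))
    stop("tuning must be named or give all ", length(defT), " values")
  new("MCMCConfig", chainLength = as.numeric(chainLength),
      logEvery = as.numeric(logEvery),
      burninFraction = as.numeric(burninFraction), seed = as.integer(seed),
      moveWeights = moveWeights, tuning = tuning)
}

## Resolve calibrations to node numbers; error if none hits the root.
.resolveCalibrations <- function(topology, calibrations) {
  if (is(calibrations, "CalibrationPrior")) calibrations <- list(calibrations)
  if (length(calibrations) == 0)
    stop("at least one calibration is required: without one the time scale ",
         "is unidentifiable")
  nodes <- vapply(calibrations, function(cal) mrcaNode(topology, cal@clade),
                  numeric(1))
  if (!rootNode(topology) %in% nodes)
    stop("a calibration on the root is required (the node-age prior is the ",
         "pure-birth process conditioned on the root age; see the methods ",
         "vignette)")
  list(nodes = as.integer(nodes),
       means = vapply(calibrations, slot, numeric(1), "mean"),
       sds = vapply(calibrations, slot, numeric(1), "sd"),
       trunc = vapply(calibrations, slot, logical(1), "truncateAtZero"))
}

#' Log prior density of a clock state
#'
#' Sum of (i) the pure-birth (Yule) node-age density conditioned on the
#' root age — non-root internal ages iid truncated-exponential with rate
#' `lambda` on `[0, rootAge]`; (ii) independent lognormal branch-rate
#' densities with arithmetic mean `mu` and log-sd `sigma`; (iii) the
#' calibration normal densities at the MRCA ages (zero-truncated where
#' flagged); (iv) the hyperpriors on `mu`, `sigma` and `lambda` documented
#' in the methods vignette. Because the non-root ages are conditioned on the
#' root, the prior marginal of a root-calibrated age is exactly its
#' truncated normal.
#'
#' @param state List with `ages` (numeric per node), `rates` (per edge),
#'   `mu`, `sigma`, `lambda`.
#' @param calibrations List of [CalibrationPrior-class] (>= 1, one on the
#'   root).
#' @param topology A [TimeTree-class] fixing the tree shape.
#' @return Log prior density; `-Inf` for an age configuration violating the
#'   topology's ordering.
#' @export
logPrior <- function(state, calibrations, topology) {
  stopifnot(is(topology, "TimeTree"))
  if (state$sigma <= 0)
    stop("sigma = 0 is degenerate (a strict clock must be simulated, not ",
         "sampled); use a positive relaxed-clock sd")
  if (state$mu <= 0 || state$lambda <= 0) stop("mu and lambda must be > 0")
  cal <- .resolveCalibrations(topology, calibrations)
  phy <- topology@phylo
  ntip <- ape::Ntip(phy)
  ages <- state$ages
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur < 0)) return(-Inf)
  rootT <- ages[ntip + 1L]
  lam <- state$lambda
  lp <- 0
  internal <- setdiff((ntip + 1L):(ntip + phy$Nnode), ntip + 1L)
  for (nd in internal)
    lp <- lp + log(lam) - lam * ages[nd] - log1p(-exp(-lam * rootT))
  for (i in seq_along(cal$nodes)) {
    a <- ages[cal$nodes[i]]
    lp <- lp + stats::dnorm(a, cal$means[i], cal$sds[i], log = TRUE)
    if (cal$trunc[i]) {
      if (a <= 0) return(-Inf)
      lp <- lp - stats::pnorm(0, cal$means[i], cal$sds[i], lower.tail = FALSE,
                              log.p = TRUE)
    }
  }
  lp <- lp + sum(stats::dlnorm(state$rates,
                               log(state$mu) - state$sigma^2 / 2,
                               state$sigma, log = TRUE))
  lp + stats::dlnorm(state$mu, .HYPER["muMeanlog"], .HYPER["muSdlog"],
                     log = TRUE) +
    stats::dexp(state$sigma, .HYPER["sigmaRate"], log = TRUE) +
    stats::dlnorm(state$lambda, .HYPER["lambdaMeanlog"],
                  .HYPER["lambdaSdlog"], log = TRUE)
}

## Crude starting rate from the mean pairwise mismatch of up to 6 sequence
## pairs (Jukes-Cantor corrected), per my of root-to-tip time.
.initialRateGuess <- function(a, rootT) {
  mat <- a@mat
  n <- nrow(mat)
  pairs <- utils::combn(seq_len(min(n, 4)), 2)
  ds <- apply(pairs, 2, function(pr) {
    x <- mat[pr[1], ]; y <- mat[pr[2], ]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    if (!any(ok)) return(NA_real_)
    p <- mean(x[ok] != y[ok])
    p <- min(p, 0.70)
    -3 / 4 * log(1 - 4 * p / 3)
  })
  d <- mean(ds, na.rm = TRUE)
  if (!is.finite(d) || d <= 0) return(0.01)
  min(max(d / (2 * rootT), 1e-4), 10)
}

#' Run the relaxed-clock dating MCMC
#'
#' Fixed-topology Metropolis-Hastings sampling of internal node ages,
#' per-branch rates and the clock hyperparameters (`mu`, `sigma`) and birth
#' rate (`lambda`), targeting the posterior under the GTR+I+Gamma pruning
#' likelihood and the prior of [logPrior()]. Moves: root-age scale,
#' internal-node age slide (uniform between the oldest child and the
#' parent), single-branch rate scale, and scale moves on `mu`, `sigma`,
#' `lambda`. A tuning warning is emitted for any move type whose acceptance
#' rate falls outside (0.05, 0.95).
#'
#' @param a An [Alignment-class] covering all tree tips (ignored when
#'   `priorOnly = TRUE`).
#' @param topology A [TimeTree-class]; its ages seed the chain after
#'   rescaling the root to the root calibration's mean.
#' @param m A [SubstitutionModel-class] (fixed during the run).
#' @param calibrations List of [CalibrationPrior-class]; one must be on the
#'   root.
#' @param cfg An [MCMCConfig-class].
#' @param priorOnly Sample from the prior (likelihood disabled).
#' @param init Optional list overriding the initial `ages`, `rates`, `mu`,
#'   `sigma`, `lambda`.
#' @return A [ClockTrace-class] with columns `generation`, `posterior`,
#'   `likelihood`, `prior`, `mu`, `sigma`, `lambda`, one `age_<node>` per
#'   internal node and one `rate_<child>` per branch.
#' @export
runMCMC <- function(a, topology, m, calibrations, cfg, priorOnly = FALSE,
                    init = NULL) {
  stopifnot(is(topology, "TimeTree"), is(m, "SubstitutionModel"),
            is(cfg, "MCMCConfig"))
  cal <- .resolveCalibrations(topology, calibrations)
  phy <- topology@phylo
  ntip <- ape::Ntip(phy)
  nint <- phy$Nnode
  root <- ntip + 1L

  if (!priorOnly) {
    stopifnot(is(a, "Alignment"))
    missing <- setdiff(phy$tip.label, rownames(a@mat))
    extra <- setdiff(rownames(a@mat), phy$tip.label)
    if (length(missing) > 0 || length(extra) > 0)
      stop("alignment/tree taxon mismatch: ",
           paste(c(missing, extra), collapse = ", "))
    mat <- a@mat[match(phy$tip.label, rownames(a@mat)), , drop = FALSE]
    pat <- .sitePatterns(mat)
    tips <- .tipPartials(pat$patterns)
    weights <- pat$weights
  } else {
    tips <- rep(list(matrix(1, 4, 1)), ntip)
    weights <- 0
  }

  Q <- buildRateMatrix(m)
  eig <- .eigenGTR(Q, m@baseFrequencies)
  mix <- siteRateMixture(m)

  ## initial state
  rootCalMean <- cal$means[match(root, cal$nodes)]
  ages0 <- topology@ages
  if (ages0[root] <= 0) stop("topology must carry positive node ages")
  ages0 <- ages0 * (rootCalMean / ages0[root])
  mu0 <- if (!priorOnly) .initialRateGuess(a, ages0[root]) else
    exp(.HYPER[["muMeanlog"]])
  state <- list(ages = ages0,
                rates = rep(mu0, nrow(phy$edge)),
                mu = mu0, sigma = 0.3,
                lambda = max(0.01, (nint - 1) /
                               max(sum(ages0[phy$edge[, 1]] -
                                       ages0[phy$edge[, 2]]), 1e-8)))
  if (!is.null(init)) state[names(init)] <- init
  if (state$sigma <= 0)
    stop("sigma = 0 is degenerate (strict clocks are simulated, not sampled)")

  set.seed(cfg@seed)
  res <- run_clock_mcmc(
               phy$edge[, 1] - 1L, phy$edge[, 2] - 1L, ntip,
               tips, as.numeric(weights),
               eig$U, eig$Uinv, eig$values, m@baseFrequencies,
               mix@rates, mix@weights,
               cal$nodes - 1L, cal$means, cal$sds, cal$trunc,
               as.numeric(.HYPER),
               state$ages, state$rates, state$mu, state$sigma, state$lambda,
               as.numeric(cfg@moveWeights), as.numeric(cfg@tuning),
               as.numeric(cfg@chainLength), as.numeric(cfg@logEvery),
               isTRUE(priorOnly))

  samples <- as.data.frame(res$trace)
  intNodes <- (ntip + 1L):(ntip + nint)
  names(samples) <- c("generation", "posterior", "likelihood", "prior",
                      "mu", "sigma", "lambda",
                      paste0("age_", intNodes),
                      paste0("rate_", phy$edge[, 2]))
  acc <- res$accepted / pmax(res$proposed, 1)
  names(acc) <- names(cfg@moveWeights)
  acc <- acc[res$proposed > 0]
  low <- acc[acc <= 0.05 | acc >= 0.95]
  if (length(low) > 0)
    warning("acceptance rate outside (0.05, 0.95) for move(s): ",
            paste(names(low), collapse = ", "),
            " - consider retuning proposal widths")
  clockTrace(samples, logEvery = cfg@logEvery, acceptance = acc)
}
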