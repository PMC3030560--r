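#' @include AllClasses.R AllGenerics.R timetree.R substmodel.R
NULL

#' Simulate a Yule (pure-birth) time tree
#'
#' Forward simulation from two lineages: while `k` lineages exist the next
#' speciation waits `Exp(k * birthRate)`; a uniformly chosen lineage splits;
#' the process stops when the next split would exceed `nTaxa` tips. All tips
#' are extant (age 0) and the tree is binary, rooted and ultrametric.
#'
#' @param nTaxa Number of tips (>= 2).
#' @param birthRate Per-lineage speciation rate (1/my), > 0.
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return A [TimeTree-class] with tips labeled `t1..tN`.
#' @examples
#' tr <- simulateYuleTree(8, 0.1, seed = 1)
#' rootAge(tr)
#' @export
simulateYuleTree <- function(nTaxa, birthRate, seed = NULL) {
  if (nTaxa < 2) stop("nTaxa must be >= 2")
  if (birthRate <= 0) stop("birthRate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  ## event times measured forward from the root (time 0 at root)
  waits <- stats::rexp(nTaxa - 1, rate = birthRate * (2:nTaxa))
  height <- sum(waits)                      # present
  splitTimes <- cumsum(waits)[-(nTaxa - 1)] # times of splits 3..nTaxa

  ## grow topology: lineage records (id); node ids assigned as created
  ## node storage: parent, two children, forward time of the split
  maxNodes <- 2 * nTaxa - 1
  childL <- integer(maxNodes); childR <- integer(maxNodes)
  splitAt <- numeric(maxNodes)
  nextId <- 1L
  mkNode <- function() { id <- nextId; nextId <<- nextId + 1L; id }
  root <- mkNode(); splitAt[root] <- 0
  lineages <- c(mkNode(), mkNode())
  childL[root] <- lineages[1]; childR[root] <- lineages[2]
  if (nTaxa > 2) {
    for (j in seq_along(splitTimes)) {
      pick <- sample.int(length(lineages), 1)
      node <- lineages[pick]
      splitAt[node] <- splitTimes[j]
      a <- mkNode(); b <- mkNode()
      childL[node] <- a; childR[node] <- b
      lineages <- c(lineages[-pick], a, b)
    }
  }
  isTip <- childL[seq_len(nextId - 1L)] == 0L
  stopifnot(sum(isTip) == nTaxa)
  num <- integer(nextId - 1L)
  num[isTip] <- seq_len(nTaxa)
  num[!isTip] <- nTaxa + seq_len(nTaxa - 1L)
  edge <- matrix(0L, 2 * nTaxa - 2, 2)
  k <- 0L
  for (i in which(!isTip)) {
    for (ch in c(childL[i], childR[i])) {
      k <- k + 1L
      edge[k, ] <- c(num[i], num[ch])
    }
  }
  ages <- numeric(maxNodes)
  ages[num[!isTip]] <- height - splitAt[!isTip]
  ages <- ages[seq_len(2 * nTaxa - 1)]
  phy <- structure(list(edge = edge, edge.length = rep(1, nrow(edge)),
                        tip.label = paste0("t", seq_len(nTaxa)),
                        Nnode = nTaxa - 1L), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  timeTree(phy, ages = ages)
}

#' Assign uncorrelated lognormal branch rates
#'
#' Each branch receives an independent lognormal rate with arithmetic mean
#' `clockMean` (log-location `log(clockMean) - clockSigma^2 / 2`) and log
#' standard deviation `clockSigma`. Branches inside `slowClade` (the crown
#' group of the MRCA of those taxa; the stem branch is excluded) have their
#' mean multiplied by `slowMultiplier`.
#'
#' @param t A [TimeTree-class].
#' @param clockMean Mean branch rate in substitutions/site/my (> 0).
#' @param clockSigma Standard deviation of log rate (>= 0); 0 gives a strict
#'   clock.
#' @param slowClade Optional character vector of tip labels defining a
#'   slower clade.
#' @param slowMultiplier Rate-mean multiplier in `(0, 1]` applied inside
#'   `slowClade`.
#' @param seed Optional integer seed.
#' @return The tree with all branch rates set.
#' @export
assignBranchRates <- function(t, clockMean, clockSigma, slowClade = NULL,
                              slowMultiplier = 1, seed = NULL) {
  stopifnot(is(t, "TimeTree"))
  if (clockMean <= 0) stop("clockMean must be > 0")
  if (clockSigma < 0) stop("clockSigma must be >= 0")
  if (slowMultiplier <= 0 || slowMultiplier > 1)
    stop("slowMultiplier must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  phy <- t@phylo
  nEdge <- nrow(phy$edge)
  means <- rep(clockMean, nEdge)
  if (!is.null(slowClade) && slowMultiplier < 1) {
    node <- if (length(slowClade) == 1)
      which(phy$tip.label == slowClade) else mrcaNode(t, slowClade)
    means[.cladeEdgeRows(phy, node)] <- clockMean * slowMultiplier
  }
  rates <- if (clockSigma == 0) means else
    stats::rlnorm(nEdge, meanlog = log(means) - clockSigma^2 / 2,
                  sdlog = clockSigma)
  branchRates(t) <- rates
  t
}

#' Simulate sequence evolution along a rate-annotated time tree
#'
#' Root states are drawn from the model's stationary frequencies; each site
#' draws a rate category from the I+Gamma mixture; states evolve branch by
#' branch with `P(rate_category x branch_rate x duration)`.
#'
#' @param t A [TimeTree-class] with all branch rates set.
#' @param m A [SubstitutionModel-class].
#' @param length Number of sites (>= 1).
#' @param seed Optional integer seed.
#' @return An [Alignment-class] of exactly `length` gap-free columns, taxa
#'   in tree tip order.
#' @export
simulateAlignment <- function(t, m, length, seed = NULL) {
  stopifnot(is(t, "TimeTree"), is(m, "SubstitutionModel"))
  if (length < 1) stop("alignment length must be >= 1")
  if (any(is.na(t@rates))) stop("every branch needs a rate before simulation")
  if (!is.null(seed)) set.seed(seed)
  phy <- t@phylo
  ntip <- ape::Ntip(phy)
  pi <- m@baseFrequencies
  Q <- buildRateMatrix(m)
  eig <- .eigenGTR(Q, pi)
  mix <- siteRateMixture(m)
  cat_of_site <- sample.int(length(mix@rates), length, replace = TRUE,
                            prob = mix@weights)
  siteRate <- mix@rates[cat_of_site]
  dur <- branchDurations(t)
  blen <- dur * t@rates

  states <- matrix(0L, ntip + phy$Nnode, length)
  root <- ntip + 1L
  states[root, ] <- sample.int(4, length, replace = TRUE, prob = pi)
  preEdges <- ape::reorder.phylo(phy, "cladewise")$edge
  edgeKey <- paste(phy$edge[, 1], phy$edge[, 2])
  for (r in seq_len(nrow(preEdges))) {
    parent <- preEdges[r, 1]; child <- preEdges[r, 2]
    e <- match(paste(parent, child), edgeKey)
    ps <- states[parent, ]
    cs <- ps
    for (rc in unique(siteRate)) {
      if (rc * blen[e] == 0) next  # invariant class or zero branch: copy
      idx <- which(siteRate == rc)
      P <- eig$U %*% (exp(eig$values * rc * blen[e]) * eig$Uinv)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      for (st in 1:4) {
        sel <- idx[ps[idx] == st]
        if (length(sel) > 0)
          cs[sel] <- sample.int(4, length(sel), replace = TRUE, prob = P[st, ])
      }
    }
    states[child, ] <- cs
  }
  bases <- c("A", "C", "G", "T")
  mat <- matrix(bases[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(mat) <- phy$tip.label
  new("Alignment", mat = mat)
}

#' Simulate life-history traits linearly related to branch rates
#'
#' `trait_i = intercept + slope * rate_i + Normal(0, noiseSd)`, truncated
#' below at `floor` (default 0.1 units) to avoid non-physical values such as
#' negative lifespans.
#'
#' @param rates Named numeric vector of per-taxon rates
#'   (substitutions/site/my).
#' @param intercept,slope Linear parameters (slope typically negative:
#'   higher rate, shorter lifespan).
#' @param noiseSd Standard deviation of additive noise (>= 0).
#' @param floor Lower truncation for the trait.
#' @param trait Name of the trait column in the result.
#' @param seed Optional integer seed.
#' @return Data frame with columns `taxon` and `<trait>`.
#' @export
simulateTraits <- function(rates, intercept, slope, noiseSd,
                           floor = 0.1, trait = "lifespan", seed = NULL) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (is.null(names(rates))) stop("rates must be named by taxon")
  if (!is.null(seed)) set.seed(seed)
  value <- intercept + slope * rates + stats::rnorm(length(rates), 0, noiseSd)
  value <- pmax(value, floor)
  out <- data.frame(taxon = names(rates), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  names(out)[2] <- trait
  out
}

#' A 24-taxon fixture mirroring the beaver mitogenome study design
#'
#' Deterministic-for-seed bundle: a 24-tip Yule tree conditioned (by
#' seed-derived rejection resampling) on containing a 6-tip clade, which is
#' assigned a rate-mean multiplier of 0.5 (the slow "beaver-like" clade);
#' uncorrelated lognormal branch rates; optionally a simulated alignment;
#' and lifespans negatively related to tip rate. Clade labels mark the slow
#' clade, the smallest ancestral clade with at least half the taxa (the
#' "mouse-clade analog") and all taxa.
#'
#' @param seed Integer seed; the whole bundle is a pure function of it.
#' @param nTaxa,slowCladeSize,birthRate,clockMean,clockSigma,slowMultiplier
#'   Generator settings; the defaults are the fixture's study conditions.
#' @param sequenceLength Alignment length in bp.
#' @param withAlignment Simulate the alignment (set `FALSE` when only tree,
#'   rates and traits are needed, e.g. for power studies on true rates).
#' @param model Substitution model used for sequence simulation.
#' @param traitIntercept,traitSlope,traitNoiseSd Lifespan model: mean
#'   lifespan `intercept + slope * tipRate` years plus noise. Defaults give
#'   long-lived slow-clade taxa (~17 y at rate 0.01) and short-lived fast
#'   taxa (~7 y at rate 0.02).
#' @return List with elements `tree` ([TimeTree-class], rates set),
#'   `alignment` ([Alignment-class] or `NULL`), `traits` (data frame),
#'   `cladeLabels` (named list of taxon sets) and `truth` (list of true
#'   parameter values).
#' @export
beaverLikeFixture <- function(seed,
                              nTaxa = 24L, slowCladeSize = 6L,
                              birthRate = 0.04, clockMean = 0.02,
                              clockSigma = 0.4, slowMultiplier = 0.5,
                              sequenceLength = 2000L,
                              withAlignment = TRUE,
                              model = substitutionModel(),
                              traitIntercept = 27, traitSlope = -1000,
                              traitNoiseSd = 4) {
  ## condition the Yule draw on a clade of exactly slowCladeSize tips
  tree <- NULL; slowNode <- NA
  for (attempt in 0:999) {
    cand <- simulateYuleTree(nTaxa, birthRate,
                             seed = (seed + 7919L * attempt) %% .Machine$integer.max)
    phy <- cand@phylo
    sizes <- vapply((nTaxa + 1L):(nTaxa + phy$Nnode), function(nd)
      length(cladeTips(cand, nd)), integer(1))
    hit <- which(sizes == slowCladeSize)
    if (length(hit) > 0) {
      tree <- cand
      slowNode <- nTaxa + hit[1]
      break
    }
  }
  if (is.null(tree)) stop("no ", slowCladeSize, "-tip clade in 1000 draws")
  slowTaxa <- cladeTips(tree, slowNode)
  tree <- assignBranchRates(tree, clockMean, clockSigma,
                            slowClade = slowTaxa,
                            slowMultiplier = slowMultiplier,
                            seed = (seed + 1L) %% .Machine$integer.max)
  ## mouse-clade analog: smallest ancestral clade with >= nTaxa/2 tips
  phy <- tree@phylo
  node <- slowNode
  repeat {
    parentRow <- which(phy$edge[, 2] == node)
    if (length(parentRow) == 0) break
    node <- phy$edge[parentRow, 1]
    if (length(cladeTips(tree, node)) >= nTaxa / 2) break
  }
  mouseClade <- cladeTips(tree, node)
  aln <- if (withAlignment)
    simulateAlignment(tree, model, sequenceLength,
                      seed = (seed + 2L) %% .Machine$integer.max) else NULL
  tips <- tipRates(tree)
  traits <- simulateTraits(stats::setNames(tips$tip_rate, tips$taxon),
                           intercept = traitIntercept, slope = traitSlope,
                           noiseSd = traitNoiseSd,
                           seed = (seed + 3L) %% .Machine$integer.max)
  list(tree = tree,
       alignment = aln,
       traits = traits,
       cladeLabels = list(slow_clade = slowTaxa,
                          mouse_clade = mouseClade,
                          all_taxa = taxonLabels(tree)),
       truth = list(seed = seed, birthRate = birthRate,
                    clockMean = clockMean, clockSigma = clockSigma,
                    slowMultiplier = slowMultiplier,
                    rootAge = rootAge(tree),
                    nodeAges = nodeAges(tree),
                    branchRates = branchRates(tree),
                    traitIntercept = traitIntercept,
                    traitSlope = traitSlope, traitNoiseSd = traitNoiseSd))
}
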