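#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GTR+I+Gamma substitution model
#'
#' The printed model-fit values of the mitogenome analysis this package
#' reproduces are a proportion of invariant sites of 0.2559 and a gamma
#' shape of 0.4721; those are the defaults here. Exchangeabilities and base
#' frequencies were not printed by that analysis, so the defaults for them
#' are synthetic (documented as such) and should be supplied from your own
#' model fit.
#'
#' @param exchangeabilities Six positive relative rates (AC, AG, AT, CG, CT,
#'   GT). Default `c(1, 4, 1, 1, 4, 1)` — a synthetic
#'   transition/transversion-biased choice, not an estimate from data.
#' @param baseFrequencies Four stationary frequencies (A, C, G, T) summing
#'   to 1. Default `c(0.32, 0.28, 0.12, 0.28)` — synthetic, mimicking the
#'   G-poor light strand of vertebrate mtDNA.
#' @param pInvariant Proportion of invariant sites in `[0, 1)`.
#' @param gammaShape Gamma shape parameter (> 0).
#' @param nCategories Number of discrete gamma categories.
#' @return A [SubstitutionModel-class].
#' @examples
#' m <- substitutionModel()
#' siteRateMixture(m)
#' @export
substitutionModel <- function(exchangeabilities = c(1, 4, 1, 1, 4, 1),
                              baseFrequencies = c(0.32, 0.28, 0.12, 0.28),
                              pInvariant = 0.2559,
                              gammaShape = 0.4721,
                              nCategories = 4L) {
  new("SubstitutionModel",
      exchangeabilities = as.numeric(exchangeabilities),
      baseFrequencies = as.numeric(baseFrequencies),
      pInvariant = as.numeric(pInvariant),
      gammaShape = as.numeric(gammaShape),
      nCategories = as.integer(nCategories))
}

setMethod("show", "SubstitutionModel", function(object) {
  cat("GTR+I+Gamma substitution model\n")
  cat("  exchangeabilities (AC,AG,AT,CG,CT,GT):",
      paste(format(object@exchangeabilities, digits = 4), collapse = " "), "\n")
  cat("  base frequencies (A,C,G,T):",
      paste(format(object@baseFrequencies, digits = 4), collapse = " "), "\n")
  cat("  p(invariant):", object@pInvariant,
      " gamma shape:", object@gammaShape,
      " categories:", object@nCategories, "\n")
})

#' Build the normalized GTR rate matrix
#'
#' Returns the 4x4 generator `Q` with `Q[i, j] = s[ij] * pi[j]` off the
#' diagonal, rows summing to zero, satisfying detailed balance
#' `pi_i Q_ij = pi_j Q_ji`, and scaled so the expected substitution rate at
#' stationarity, `-sum(pi_i Q_ii)`, equals one.
#'
#' @param m A [SubstitutionModel-class].
#' @return 4x4 numeric matrix with dimnames `A,C,G,T`.
#' @export
buildRateMatrix <- function(m) {
  stopifnot(is(m, "SubstitutionModel"))
  s <- m@exchangeabilities
  pi <- m@baseFrequencies
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- s[k] * pi[j]
    Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

## Eigendecomposition of the reversible generator via its symmetrized form
## B = D^{1/2} Q D^{-1/2}; returns U, U^{-1}, eigenvalues with
## P(t) = U diag(exp(d t)) Uinv. Numerically stable for 4-state chains.
.eigenGTR <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))  # diag(d) Q diag(1/d), symmetric by reversibility
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- diag(1 / d) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(d)
  list(U = U, Uinv = Uinv, values = eig$values)
}

#' Transition probability matrix of the model
#'
#' `P(t) = exp(Q t)` for branch length `t` in expected substitutions per
#' site, computed by eigendecomposition of the symmetrized reversible
#' generator.
#'
#' @param Q Generator from [buildRateMatrix()] (its stationary frequencies
#'   are recovered from the detailed-balance structure).
#' @param t Expected substitutions per site (>= 0).
#' @param pi Optional stationary frequencies; inferred from `Q` when `NULL`.
#' @return 4x4 row-stochastic matrix.
#' @export
transitionProbabilities <- function(Q, t, pi = NULL) {
  if (t < 0) stop("branch length t must be >= 0")
  if (is.null(pi)) pi <- .stationaryFromQ(Q)
  e <- .eigenGTR(Q, pi)
  P <- e$U %*% (exp(e$values * t) * e$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

## Stationary distribution of a reversible generator (left null vector).
.stationaryFromQ <- function(Q) {
  ns <- t(Q)
  ns <- rbind(ns, rep(1, 4))
  pi <- stats::lsfit(ns, c(0, 0, 0, 0, 1), intercept = FALSE)$coefficients
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Discrete site-rate mixture of a model
#'
#' With `pInvariant > 0` the mixture has one zero-rate class of weight
#' `pInvariant`; the remaining `nCategories` classes have equal weight
#' `(1 - pInvariant) / nCategories` and carry the means of equal-probability
#' slices of `Gamma(shape, shape)`, rescaled so the full mixture has mean
#' one.
#'
#' @param m A [SubstitutionModel-class].
#' @return A [SiteRateMixture-class].
#' @export
siteRateMixture <- function(m) {
  stopifnot(is(m, "SubstitutionModel"))
  a <- m@gammaShape
  k <- m@nCategories
  pInv <- m@pInvariant
  ## category means of equal-probability slices of Gamma(a, a) (mean 1):
  ## E[X | q_i < X < q_{i+1}] * k = k * (F_{a+1}(q_{i+1}) - F_{a+1}(q_i))
  ## using the gamma identity x f_a(x) = f_{a+1}(x) (rates equal).
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = a, rate = a)
  upper <- stats::pgamma(bounds[-1], shape = a + 1, rate = a)
  lower <- stats::pgamma(bounds[-(k + 1)], shape = a + 1, rate = a)
  gammaRates <- k * (upper - lower)
  gammaRates <- gammaRates / sum(gammaRates / k)  # guard tiny numeric drift
  if (pInv > 0) {
    rates <- c(0, gammaRates / (1 - pInv))
    weights <- c(pInv, rep((1 - pInv) / k, k))
  } else {
    rates <- gammaRates
    weights <- rep(1 / k, k)
  }
  new("SiteRateMixture", rates = rates, weights = weights)
}

## IUPAC partial-observation vectors: each compatible base has conditional
## likelihood 1; gaps and '?' are fully missing.
.IUPAC_PARTIALS <- local({
  codes <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
                `?` = c("A", "C", "G", "T"))
  bases <- c("A", "C", "G", "T")
  out <- lapply(codes, function(x) as.numeric(bases %in% x))
  names(out) <- names(codes)
  out
})

## Compress alignment columns into unique site patterns.
## Returns list(patterns = taxa x npat character matrix, weights).
.sitePatterns <- function(mat) {
  if (ncol(mat) == 0)
    return(list(patterns = mat, weights = numeric(0)))
  key <- apply(mat, 2, paste, collapse = "\r")
  tab <- table(factor(key, levels = unique(key)))
  list(patterns = mat[, match(names(tab), key), drop = FALSE],
       weights = as.numeric(tab))
}

## Tip partial-likelihood matrices (4 x npat) for each taxon.
.tipPartials <- function(patterns) {
  lapply(seq_len(nrow(patterns)), function(i) {
    vapply(patterns[i, ], function(ch) {
      p <- .IUPAC_PARTIALS[[ch]]
      if (is.null(p)) stop("invalid state '", ch, "' in alignment")
      p
    }, numeric(4))
  })
}

#' Log-likelihood of an alignment on a rate-annotated time tree
#'
#' Felsenstein pruning under GTR+I+Gamma. Branch lengths in expected
#' substitutions per site are `branch rate x branch duration`; IUPAC
#' ambiguity codes are partial observations and gaps are fully missing.
#' Per-node log-scaling of the partials keeps mitogenome-scale alignments
#' away from underflow.
#'
#' This is the reference (pure R) implementation; [runMCMC()] uses an
#' equivalent compiled engine and the two are held to each other by the
#' package's no-drift tests.
#'
#' @param a An [Alignment-class]; its taxa must all appear in the tree.
#' @param t A [TimeTree-class] with every branch rate annotated.
#' @param m A [SubstitutionModel-class].
#' @return The log-likelihood (a finite scalar for any observable pattern).
#' @export
logLikelihood <- function(a, t, m) {
  stopifnot(is(a, "Alignment"), is(t, "TimeTree"), is(m, "SubstitutionModel"))
  phy <- t@phylo
  missing <- setdiff(rownames(a@mat), phy$tip.label)
  if (length(missing) > 0)
    stop("alignment taxa absent from tree: ", paste(missing, collapse = ", "))
  if (any(is.na(t@rates)))
    stop("every branch must carry a rate annotation")
  if (ncol(a@mat) == 0) return(0)

  ntip <- ape::Ntip(phy)
  present <- phy$tip.label %in% rownames(a@mat)
  if (!all(present))
    stop("tree tips without sequences: ",
         paste(phy$tip.label[!present], collapse = ", "))
  mat <- a@mat[match(phy$tip.label, rownames(a@mat)), , drop = FALSE]
  pat <- .sitePatterns(mat)
  tips <- .tipPartials(pat$patterns)
  npat <- length(pat$weights)

  Q <- buildRateMatrix(m)
  pi <- m@baseFrequencies
  eig <- .eigenGTR(Q, pi)
  mix <- siteRateMixture(m)
  dur <- branchDurations(t)
  blen <- dur * t@rates

  edge <- phy$edge
  childEdges <- split(seq_len(nrow(edge)), edge[, 1])
  ## internal nodes in postorder (children before parents)
  postorder <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1])

  logSite <- matrix(0, length(mix@rates), npat)  # per-category log site lik
  for (ci in seq_along(mix@rates)) {
    r <- mix@rates[ci]
    Pmats <- lapply(blen * r, function(x) {
      P <- eig$U %*% (exp(eig$values * x) * eig$Uinv)
      P[P < 0] <- 0
      P
    })
    partial <- vector("list", ntip + phy$Nnode)
    scaleLog <- rep(0, npat)
    for (node in postorder) {
      p <- matrix(1, 4, npat)
      for (e in childEdges[[as.character(node)]]) {
        child <- edge[e, 2]
        cp <- if (child <= ntip) tips[[child]] else partial[[child]]
        p <- p * (Pmats[[e]] %*% cp)
      }
      mx <- apply(p, 2, max)
      ok <- mx > 0
      mx[!ok] <- 1
      p <- p / rep(mx, each = 4)
      scaleLog <- scaleLog + ifelse(ok, log(mx), -Inf)
      partial[[node]] <- p
    }
    root <- ntip + 1L
    logSite[ci, ] <- log(colSums(pi * partial[[root]])) + scaleLog
  }
  ## combine categories: log sum_c w_c exp(logSite_c)
  mxs <- apply(logSite, 2, max)
  comb <- mxs + log(colSums(mix@weights * exp(sweep(logSite, 2, mxs))))
  sum(pat$weights * comb)
}
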