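# Shared fixtures and independent oracles used across the test files.

# Three-taxon time tree ((A,B),C) with unit/2-unit durations.
threeTaxonTree <- function(rates = rep(0.1, 4)) {
  tr <- timeTree(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  branchRates(tr) <- rates
  tr
}

# Independent pruning oracle: brute-force enumeration over all internal
# node state assignments and site-rate categories. Uses plain (non
# symmetrized) eigen() for the matrix exponential so that it shares no code
# path with the package's likelihood.
bruteForceLogLik <- function(a, tr, m) {
  phy <- asPhylo(tr)
  ntip <- ape::Ntip(phy)
  Q <- buildRateMatrix(m)
  pi <- m@baseFrequencies
  mix <- siteRateMixture(m)
  blen <- branchDurations(tr) * branchRates(tr)
  mat <- alignmentMatrix(a)
  mat <- mat[match(phy$tip.label, rownames(mat)), , drop = FALSE]
  code <- c(A = 1, C = 2, G = 3, T = 4)
  nInt <- phy$Nnode
  expmQ <- function(x) {
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * x)) %*% solve(e$vectors))
  }
  total <- 0
  for (site in seq_len(ncol(mat))) {
    siteL <- 0
    for (ci in seq_along(mix@rates)) {
      P <- lapply(blen * mix@rates[ci], expmQ)
      grid <- as.matrix(expand.grid(rep(list(1:4), nInt)))
      s <- 0
      for (g in seq_len(nrow(grid))) {
        states <- grid[g, ]
        pr <- pi[states[1]]  # root is the first internal node
        for (e in seq_len(nrow(phy$edge))) {
          par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
          cs <- if (ch <= ntip) code[[mat[ch, site]]] else states[ch - ntip]
          pr <- pr * P[[e]][states[par - ntip], cs]
        }
        s <- s + pr
      }
      siteL <- siteL + mix@weights[ci] * s
    }
    total <- total + log(siteL)
  }
  total
}

# Jukes-Cantor model (equal everything, no I, one category).
jcModel <- function() {
  substitutionModel(exchangeabilities = rep(1, 6),
                    baseFrequencies = rep(0.25, 4),
                    pInvariant = 0, gammaShape = 1, nCategories = 1L)
}

# Small random alignment over plain ACGT.
randomAlignment <- function(nTaxa, len, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(nTaxa), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", seq_len(nTaxa))
  alignment(seqs)
}

# 12-taxon strict-ish clock recovery fixture: root rescaled to 10 my.
recoveryFixture <- function(seed, sigma = 0.05, len = 1200,
                            model = substitutionModel()) {
  tr <- simulateYuleTree(12, 0.21, seed = seed)
  tr <- timeTree(asPhylo(tr), ages = nodeAges(tr) * (10 / rootAge(tr)))
  tr <- assignBranchRates(tr, 0.02, sigma, seed = seed + 500L)
  a <- simulateAlignment(tr, model, len, seed = seed + 900L)
  list(tree = tr, alignment = a, trueRate = 0.02, trueRootAge = 10)
}
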