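test_that("a zero-length cherry reduces to stationary site probabilities", {
  # both tips identical, zero durations: L per site = pi of the base
  tr <- timeTree(ape::read.tree(text = "(A:0,B:0);"))
  branchRates(tr) <- c(0.1, 0.1)
  a <- alignment(c(A = "ACGT", B = "ACGT"))
  expect_equal(logLikelihood(a, tr, jcModel()), 4 * log(0.25),
               tolerance = 1e-12)
  m <- substitutionModel(pInvariant = 0, gammaShape = 1, nCategories = 1L)
  expect_equal(logLikelihood(a, tr, m), sum(log(m@baseFrequencies)),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on a 3-taxon tree", {
  a <- alignment(c(A = "ACGTT", B = "ACGAA", C = "CCGTA"))
  for (m in list(jcModel(), substitutionModel())) {
    tr <- threeTaxonTree(rates = c(0.05, 0.12, 0.3, 0.08))
    expect_equal(logLikelihood(a, tr, m), bruteForceLogLik(a, tr, m),
                 tolerance = 1e-10)
  }
})

test_that("the root position is irrelevant under a reversible model", {
  # pulley principle: redistributing expected substitutions between the two
  # root-adjacent branches leaves the likelihood unchanged
  a <- alignment(c(A = "ACGTTACGGA", B = "ACGAAACGTA", C = "CCGTACTGTA"))
  m <- substitutionModel()
  # edge order (cladewise): stem AB, tip A, tip B, tip C
  base <- threeTaxonTree(rates = c(0.10, 0.05, 0.05, 0.10))
  # stem (AB) duration 1 at rate 0.10, C duration 2 at rate 0.10:
  # move 0.05 expected substitutions from the C branch onto the stem
  shifted <- threeTaxonTree(rates = c(0.15, 0.05, 0.05, 0.075))
  expect_equal(logLikelihood(a, base, m), logLikelihood(a, shifted, m),
               tolerance = 1e-10)
})

test_that("likelihood decreases as mismatches accumulate on a cherry", {
  tr <- timeTree(ape::read.tree(text = "(A:1,B:1);"))
  branchRates(tr) <- c(0.05, 0.05)
  m <- substitutionModel()
  seqB <- c("ACGTACGTAC", "ACGTACGTAA", "ACGTACATAA", "ACTTACATAA",
            "GCTTACATAA")
  lls <- vapply(seqB, function(s)
    logLikelihood(alignment(c(A = "ACGTACGTAC", B = s)), tr, m), numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("likelihood is invariant to taxon order in the alignment", {
  fx <- recoveryFixture(21, len = 80)
  m <- substitutionModel()
  a <- fx$alignment
  perm <- alignment(alignmentMatrix(a)[rev(seq_len(nTaxa(a))), ,
                                       drop = FALSE])
  expect_equal(logLikelihood(perm, fx$tree, m),
               logLikelihood(a, fx$tree, m), tolerance = 1e-12)
})

test_that("IUPAC ambiguity sums the compatible-base likelihoods; gaps are missing", {
  tr <- timeTree(ape::read.tree(text = "(A:1,B:1);"))
  branchRates(tr) <- c(0.03, 0.07)
  m <- substitutionModel()
  lik <- function(sB) exp(logLikelihood(alignment(c(A = "A", B = sB)), tr, m))
  expect_equal(lik("R"), lik("A") + lik("G"), tolerance = 1e-12)
  # a gap column contributes only the marginal of the observed taxon
  expect_equal(lik("-"), sum(vapply(c("A", "C", "G", "T"), lik, numeric(1))),
               tolerance = 1e-12)
})

test_that("likelihood agrees with an independent GTR+I+Gamma implementation", {
  skip_if_not_installed("phangorn")
  fx <- recoveryFixture(31, sigma = 0.3, len = 400)
  m <- substitutionModel()
  phy <- asPhylo(fx$tree)
  phy$edge.length <- branchDurations(fx$tree) * branchRates(fx$tree)
  fit <- phangorn::pml(phy,
                       phangorn::phyDat(alignmentMatrix(fx$alignment),
                                        type = "DNA"),
                       bf = m@baseFrequencies, Q = m@exchangeabilities,
                       inv = m@pInvariant, k = m@nCategories,
                       shape = m@gammaShape)
  expect_equal(logLikelihood(fx$alignment, fx$tree, m), fit$logLik,
               tolerance = 1e-6)
})

test_that("taxon mismatches and missing rates are reported", {
  tr <- threeTaxonTree()
  a <- alignment(c(A = "ACGT", B = "ACGT", D = "ACGT"))
  expect_error(logLikelihood(a, tr, jcModel()), "absent from tree")
  tr2 <- threeTaxonTree()
  branchRates(tr2) <- c(0.1, NA, 0.1, 0.1)
  aa <- alignment(c(A = "ACGT", B = "ACGT", C = "ACGT"))
  expect_error(logLikelihood(aa, tr2, jcModel()), "rate annotation")
})
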