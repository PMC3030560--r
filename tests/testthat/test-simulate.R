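test_that("Yule trees have the promised shape and tip counts", {
  for (n in c(2, 5, 24)) {
    tr <- simulateYuleTree(n, 0.1, seed = n)
    expect_equal(nTaxa(tr), n)
    expect_equal(asPhylo(tr)$Nnode, n - 1)
    expect_equal(nrow(asPhylo(tr)$edge), 2 * n - 2)
    expect_true(ape::is.ultrametric(asPhylo(tr), tol = 1e-8))
    expect_true(all(nodeAges(tr)[seq_len(n)] == 0))
  }
  expect_error(simulateYuleTree(1, 0.1), ">= 2")
  expect_error(simulateYuleTree(4, 0), "> 0")
})

test_that("Yule waiting times match the exponential means", {
  lambda <- 0.5
  set.seed(77)
  # with 2 lineages the wait to the next split is Exp(2 lambda): the n = 2
  # root age is exactly that wait
  roots <- replicate(4000, rootAge(simulateYuleTree(2, lambda)))
  expect_equal(mean(roots), 1 / (2 * lambda), tolerance = 0.05)
  # while k lineages exist the wait is Exp(k lambda): for n = 4 the root age
  # is the sum of the k = 2, 3, 4 waits
  roots4 <- replicate(4000, rootAge(simulateYuleTree(4, lambda)))
  expected <- sum(1 / (lambda * 2:4))
  expect_equal(mean(roots4), expected, tolerance = 0.05)
})

test_that("branch rates follow the mean/log-sd lognormal parameterization", {
  tr <- simulateYuleTree(24, 0.04, seed = 2)
  strict <- assignBranchRates(tr, 0.02, 0)
  expect_equal(branchRates(strict), rep(0.02, 46), tolerance = 1e-15)

  set.seed(5)
  rates <- unlist(lapply(1:220, function(i)
    branchRates(assignBranchRates(tr, 0.02, 0.4))))
  expect_gt(length(rates), 10000)
  expect_equal(mean(rates), 0.02, tolerance = 0.02)  # within 2 percent
  expect_equal(sd(log(rates)), 0.4, tolerance = 0.02)
})

test_that("a slow clade multiplier halves the clade's mean rate", {
  tr <- simulateYuleTree(24, 0.04, seed = 8)
  phy <- asPhylo(tr)
  parentOfT1 <- phy$edge[match(match("t1", phy$tip.label), phy$edge[, 2]), 1]
  clade <- cladeTips(tr, parentOfT1)
  set.seed(6)
  inRates <- c(); outRates <- c()
  for (i in 1:200) {
    rt <- assignBranchRates(tr, 0.02, 0.4, slowClade = clade,
                            slowMultiplier = 0.5)
    tips <- tipRates(rt)
    inRates <- c(inRates, tips$tip_rate[tips$taxon %in% clade])
    outRates <- c(outRates, tips$tip_rate[!tips$taxon %in% clade])
  }
  expect_equal(mean(inRates) / mean(outRates), 0.5, tolerance = 0.05)
})

test_that("simulated alignments have the right size and degenerate limits", {
  tr <- assignBranchRates(simulateYuleTree(6, 0.2, seed = 3), 0.02, 0.3,
                          seed = 4)
  a <- simulateAlignment(tr, substitutionModel(), 137, seed = 5)
  expect_equal(alignmentLength(a), 137)
  expect_equal(nTaxa(a), 6)
  expect_true(all(alignmentMatrix(a) %in% c("A", "C", "G", "T")))

  flat <- timeTree(asPhylo(tr), ages = rep(0, 11))
  branchRates(flat) <- rep(0.02, 10)
  a0 <- simulateAlignment(flat, substitutionModel(), 50, seed = 6)
  m <- alignmentMatrix(a0)
  for (i in 2:6) expect_identical(m[i, ], m[1, ])

  noRates <- simulateYuleTree(4, 0.2, seed = 1)
  expect_error(simulateAlignment(noRates, substitutionModel(), 10),
               "rate")
})

test_that("two-taxon pattern frequencies match stationarity x transition", {
  m <- jcModel()
  tr <- timeTree(ape::read.tree(text = "(A:2,B:2);"))
  branchRates(tr) <- c(0.05, 0.05)
  n <- 50000
  a <- simulateAlignment(tr, m, n, seed = 9)
  mat <- alignmentMatrix(a)
  Q <- buildRateMatrix(m)
  # A and B are both 0.1 expected substitutions from the root: joint
  # probability = sum_r pi_r P(r->i, 0.1) P(r->j, 0.1)
  P <- transitionProbabilities(Q, 0.1)
  joint <- t(P) %*% diag(rep(0.25, 4)) %*% P
  bases <- c("A", "C", "G", "T")
  for (i in 1:4) for (j in 1:4) {
    obs <- mean(mat[1, ] == bases[i] & mat[2, ] == bases[j])
    p <- joint[i, j]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-12)
  }
})

test_that("trait simulation is exact without noise and consistent with it", {
  rates <- setNames(seq(0.005, 0.03, length.out = 20), paste0("t", 1:20))
  tt <- simulateTraits(rates, intercept = 30, slope = -800, noiseSd = 0)
  fit <- linearRegression(tt$lifespan, unname(rates))
  # x and y swapped on purpose: recovering the inverse map is exact too
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  fit2 <- linearRegression(unname(rates), tt$lifespan)
  expect_equal(fit2@slope, -800, tolerance = 1e-9)
  expect_equal(fit2@intercept, 30, tolerance = 1e-9)

  set.seed(11)
  slopes <- replicate(40, {
    t2 <- simulateTraits(rates, 30, -800, noiseSd = 2)
    linearRegression(unname(rates), t2$lifespan)@slope
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-800)), 3 * se + 30)
  expect_error(simulateTraits(rates, 30, -800, noiseSd = -1), ">= 0")
})

test_that("the 24-taxon fixture is deterministic with a 6-tip slow clade", {
  fx <- beaverLikeFixture(4, withAlignment = TRUE, sequenceLength = 200)
  expect_equal(nTaxa(fx$tree), 24)
  expect_length(fx$cladeLabels$slow_clade, 6)
  expect_length(fx$cladeLabels$all_taxa, 24)
  expect_gte(length(fx$cladeLabels$mouse_clade), 12)
  expect_true(all(fx$cladeLabels$slow_clade %in% fx$cladeLabels$mouse_clade))
  expect_equal(alignmentLength(fx$alignment), 200)

  fx2 <- beaverLikeFixture(4, withAlignment = TRUE, sequenceLength = 200)
  expect_identical(alignmentMatrix(fx$alignment),
                   alignmentMatrix(fx2$alignment))
  expect_identical(branchRates(fx$tree), branchRates(fx2$tree))
  expect_identical(fx$traits, fx2$traits)

  # lifespans decline with tip rate by construction
  tips <- tipRates(fx$tree)
  merged <- merge(tips, fx$traits, by = "taxon")
  expect_lt(cor(merged$tip_rate, merged$lifespan), 0)
})
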