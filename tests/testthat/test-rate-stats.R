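test_that("tip rates read the terminal branches", {
  tr <- parseTimeTree("(A[&rate=0.01]:1,B[&rate=0.02]:1);")
  tips <- tipRates(tr)
  expect_equal(setNames(tips$tip_rate, tips$taxon), c(A = 0.01, B = 0.02))

  bare <- timeTree(ape::read.tree(text = "(A:1,B:1);"))
  expect_error(tipRates(bare), "unannotated")
})

test_that("path-averaged rates are plain means over the tip-to-ancestor path", {
  # caterpillar (((A,B),C),D): path from root to A has 3 branches
  tr <- timeTree(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))
  phy <- asPhylo(tr)
  rates <- numeric(nrow(phy$edge))
  # rate by child node: A gets 0.03, its parent edge 0.02, grandparent 0.01
  nodeRate <- c(A = 0.03, B = 0.04, C = 0.05, D = 0.06)
  for (e in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[e, 2]
    rates[e] <- if (ch <= 4) nodeRate[[phy$tip.label[ch]]] else
      if (ch == 6) 0.01 else 0.02  # node 6 = (ABC), node 7 = (AB)
  }
  branchRates(tr) <- rates
  avg <- averagedRates(tr, taxa = c("A", "B", "C", "D"), ancestor = "root")
  got <- setNames(avg$averaged_rate, avg$taxon)
  expect_equal(got[["A"]], mean(c(0.03, 0.02, 0.01)))  # = 0.02 by hand
  expect_equal(got[["D"]], 0.06)  # one-branch path equals the tip rate

  # equals tip rate when the ancestor is the direct parent
  ab <- averagedRates(tr, taxa = c("A", "B"), ancestor = c("A", "B"))
  expect_equal(setNames(ab$averaged_rate, ab$taxon),
               c(A = 0.03, B = 0.04))

  # constant rates average to that constant; stem option changes the path
  flat <- tr; branchRates(flat) <- rep(0.07, 6)
  af <- averagedRates(flat, ancestor = "root")
  expect_equal(af$averaged_rate, rep(0.07, 4))

  expect_error(averagedRates(tr, taxa = "D", ancestor = c("A", "B")),
               "not ancestral")
})

test_that("averaged rates are bounded by the path's extremes and match the
           time-weighted variant on equal durations", {
  tr <- assignBranchRates(simulateYuleTree(12, 0.2, seed = 13), 0.02, 0.5,
                          seed = 14)
  avg <- averagedRates(tr, ancestor = "root")
  expect_true(all(avg$averaged_rate >= min(branchRates(tr)) - 1e-12))
  expect_true(all(avg$averaged_rate <= max(branchRates(tr)) + 1e-12))

  # equal durations: duration-weighted mean collapses to the plain mean
  eq <- timeTree(ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);"))
  branchRates(eq) <- c(0.01, 0.05, 0.02, 0.03, 0.04, 0.06)
  # the A path has branch durations 1,1,1 -> equal
  a1 <- averagedRates(eq, taxa = "A", ancestor = "root")$averaged_rate
  a2 <- averagedRates(eq, taxa = "A", ancestor = "root",
                      timeWeighted = TRUE)$averaged_rate
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("rank-sum U and exact p match hand enumeration", {
  res <- rankSumTest(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res@U, 0)
  expect_equal(res@pValue, 2 / choose(6, 3))  # = 0.1
  expect_equal(res@method, "exact")

  ties <- rankSumTest(c(5, 5, 5), c(5, 5, 5), mode = "normal")
  expect_equal(ties@U, 4.5)  # n1 n2 / 2
  expect_equal(ties@pValue, 1)

  expect_error(rankSumTest(numeric(0), 1), "non-empty")
  expect_error(rankSumTest(c(1, 2, 2), c(2, 3), mode = "exact"), "ties")
})

test_that("U(x, y) + U(y, x) = n1 n2 and the normal p matches wilcox.test", {
  set.seed(8)
  for (i in 1:25) {
    x <- sample(1:10, sample(3:8, 1), replace = TRUE)
    y <- sample(1:10, sample(3:8, 1), replace = TRUE)
    u1 <- rankSumTest(x, y, mode = "normal")
    u2 <- rankSumTest(y, x, mode = "normal")
    expect_equal(u1@U + u2@U, length(x) * length(y))
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(u1@U, unname(ref$statistic))  # same x-over-y pair count
    expect_equal(u1@pValue, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation converges to the exact tail", {
  set.seed(12)
  diffs <- replicate(100, {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    abs(rankSumTest(x, y, mode = "normal")@pValue -
        rankSumTest(x, y, mode = "exact")@pValue)
  })
  # the 0.5 continuity correction (needed to reproduce published p-values)
  # leaves a worst-case gap slightly above 0.01 at n1 = n2 = 8
  expect_lt(max(diffs), 0.015)
  expect_lt(median(diffs), 0.01)
})

test_that("complete separation at the study's group sizes reproduces the
           printed significance", {
  # 6 slow-clade taxa all below 6 comparison taxa: U (slow over rest) = 0,
  # i.e. rest-over-slow = 36 = n1 n2, the strongest possible configuration;
  # the continuity-corrected normal two-sided p is ~0.005
  slow <- c(0.004, 0.005, 0.006, 0.007, 0.008, 0.009)
  rest <- c(0.012, 0.015, 0.018, 0.021, 0.024, 0.027)
  res <- rankSumTest(rest, slow, mode = "normal")
  expect_equal(res@U, 36)
  expect_equal(res@pValue, 0.004998, tolerance = 0.03)
})

test_that("collapsing a group averages it into one point, idempotently", {
  pts <- data.frame(taxon = paste0("b", 1:7),
                    group = c(rep("beaver", 6), "other"),
                    rate = c(1:6 / 100, 0.2),
                    lifespan = c(20, 22, 24, 26, 28, 30, 5),
                    mass = c(NA, NA, NA, NA, NA, NA, 100))
  out <- collapseGroup(pts, "beaver")
  expect_equal(nrow(out), 2)
  b <- out[out$group == "beaver", ]
  expect_equal(b$rate, mean(1:6 / 100))
  expect_equal(b$lifespan, 25)
  expect_true(is.na(b$mass))  # all-missing trait stays missing

  again <- collapseGroup(out, "beaver")
  expect_equal(again[order(again$taxon), -1], out[order(out$taxon), -1],
               ignore_attr = TRUE)

  single <- collapseGroup(pts, "other")
  expect_equal(nrow(single), nrow(pts))
  expect_error(collapseGroup(pts, "nope"), "empty group")
})

test_that("OLS matches the closed form and its invariants", {
  fit <- linearRegression(c(1, 2, 3), c(1, 3, 4))
  expect_equal(fit@slope, 1.5, tolerance = 1e-12)
  expect_equal(fit@intercept, -1 / 3, tolerance = 1e-12)
  expect_equal(fit@rSquared, 27 / 28, tolerance = 1e-12)

  perfect <- linearRegression(1:10, 2 * (1:10) + 1)
  expect_equal(perfect@rSquared, 1, tolerance = 1e-12)
  expect_lt(perfect@pValue, 1e-12)

  # R^2 equals the squared sample correlation
  set.seed(4)
  x <- rnorm(30); y <- 0.3 * x + rnorm(30)
  expect_equal(linearRegression(x, y)@rSquared, cor(x, y)^2,
               tolerance = 1e-12)

  # pairwise deletion of missing values
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(linearRegression(xm, ym)@n, 30L)

  expect_error(linearRegression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(linearRegression(1:2, 1:2), ">= 3")
})

test_that("the full rate-comparison report has the study's shape", {
  fx <- beaverLikeFixture(3, withAlignment = FALSE)
  rep <- rateComparisonReport(fx$tree, fx$cladeLabels$slow_clade,
                              fx$cladeLabels[c("mouse_clade", "all_taxa")],
                              traits = fx$traits)
  expect_equal(nrow(rep$tests), 4)  # 2 comparisons x {tip, averaged}
  expect_true(all(is.finite(rep$tests$U)))
  expect_true(all(rep$tests$p_value >= 0 & rep$tests$p_value <= 1))
  expect_equal(nrow(rep$regressions), 2)  # 1 trait x {tip, averaged}
  expect_true(all(is.finite(rep$regressions$r_squared)))
  # collapsing 6 beavers into one point leaves n = 24 - 6 + 1 = 19
  expect_equal(unique(rep$regressions$n), 19L)
})
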