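mkTrace <- function(n, seed = 1, le = 10) {
  set.seed(seed)
  clockTrace(data.frame(generation = seq(0, by = le, length.out = n),
                        x = rnorm(n), y = runif(n)), logEvery = le)
}

test_that("combining traces removes per-trace burn-in then concatenates", {
  traces <- lapply(1:3, function(i) mkTrace(1000, seed = i))
  out <- combineTraces(traces, 0.10)
  expect_equal(nrow(traceSamples(out)), 2700)
  expect_equal(diff(traceSamples(out)$generation)[1], 10)
  expect_true(all(diff(traceSamples(out)$generation) > 0))

  one <- combineTraces(list(traces[[1]]), 0.10)
  expect_equal(traceSamples(one)$x, traceSamples(traces[[1]])$x[101:1000])

  # combined mean equals the mean of the independently post-burnin parts
  parts <- lapply(traces, function(tr) traceSamples(tr)$x[101:1000])
  expect_equal(mean(traceSamples(out)$x), mean(unlist(parts)),
               tolerance = 1e-12)
})

test_that("trace combining rejects mismatched columns", {
  a <- mkTrace(100)
  b <- clockTrace(data.frame(generation = 0:99, z = rnorm(100)))
  expect_error(combineTraces(list(a, b), 0.1), "column set")
})

test_that("ESS is near n for white noise and near theory for AR(1)", {
  set.seed(42)
  x <- rnorm(10000)
  expect_equal(effectiveSampleSize(x), 10000, tolerance = 0.10)

  phi <- 0.9
  n <- 50000
  ar <- as.numeric(arima.sim(list(ar = phi), n))
  expect_equal(effectiveSampleSize(ar), n * (1 - phi) / (1 + phi),
               tolerance = 0.15)

  expect_equal(effectiveSampleSize(rev(ar)), effectiveSampleSize(ar))
  expect_error(effectiveSampleSize(rep(1, 100)), "constant")
  expect_error(effectiveSampleSize(1:5), "short")
})

test_that("ESS agrees with an established diagnostic implementation", {
  skip_if_not_installed("coda")
  set.seed(3)
  ar <- as.numeric(arima.sim(list(ar = 0.8), 20000))
  mine <- effectiveSampleSize(ar)
  ref <- unname(coda::effectiveSize(coda::mcmc(ar)))
  expect_equal(mine, ref, tolerance = 0.2)
})

test_that("HPD intervals are the shortest windows of the right mass", {
  expect_equal(diff(hpdInterval(1:100, 0.95)), 94, ignore_attr = TRUE)
  expect_equal(hpdInterval(rep(3, 10), 0.95), c(3, 3))

  # brute-force oracle: exhaustive search over all windows of ceil(mass n)
  bruteHPD <- function(v, mass) {
    s <- sort(v)
    m <- ceiling(mass * length(s))
    best <- c(-Inf, Inf)
    for (i in seq_len(length(s) - m + 1)) {
      if (s[i + m - 1] - s[i] < best[2] - best[1])
        best <- c(s[i], s[i + m - 1])
    }
    best
  }
  set.seed(7)
  for (i in 1:20) {
    v <- switch(1 + i %% 3, rnorm(200), rexp(200), c(rnorm(100), rnorm(50, 8)))
    for (mass in c(0.5, 0.9, 0.95))
      expect_equal(hpdInterval(v, mass), bruteHPD(v, mass))
  }
  expect_error(hpdInterval(1, 0.95), ">= 2")
  expect_error(hpdInterval(1:10, 1), "mass")
})

test_that("clade-age summaries report mean, median and HPD", {
  tr <- clockTrace(data.frame(generation = 0:99, age_13 = rep(6.5, 100)))
  s <- summarizeCladeAge(tr, "age_13")
  expect_equal(s$mean, 6.5)
  expect_equal(s$median, 6.5)
  expect_equal(s$hpd, c(6.5, 6.5))
  expect_error(summarizeCladeAge(tr, "age_99"), "unknown")
})

test_that("posterior annotation reproduces a single logged state exactly", {
  topo <- assignBranchRates(simulateYuleTree(5, 0.3, seed = 2), 0.02, 0.2,
                            seed = 3)
  phy <- asPhylo(topo)
  row <- data.frame(generation = 0)
  for (nd in 6:9) row[[paste0("age_", nd)]] <- nodeAges(topo)[nd]
  for (e in seq_len(nrow(phy$edge)))
    row[[paste0("rate_", phy$edge[e, 2])]] <- branchRates(topo)[e]
  ann <- annotatePosteriorRates(clockTrace(row), topo)
  expect_equal(nodeAges(ann), nodeAges(topo), tolerance = 1e-12)
  expect_equal(branchRates(ann), branchRates(topo), tolerance = 1e-12)

  # annotated tree round-trips through the Newick layer unchanged
  f <- withr::local_tempfile(fileext = ".nwk")
  writeTimeTree(ann, f)
  back <- readTimeTree(f)
  expect_equal(sort(nodeAges(back)), sort(nodeAges(ann)), tolerance = 1e-9)
  expect_equal(sort(branchRates(back)), sort(branchRates(ann)),
               tolerance = 1e-9)

  expect_error(annotatePosteriorRates(clockTrace(row[, -2]), topo),
               "missing age column")
})

test_that("traces round-trip through TSV", {
  tr <- mkTrace(50, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTrace(tr, f)
  back <- readTrace(f)
  expect_equal(traceSamples(back)$x, traceSamples(tr)$x, tolerance = 1e-12)
  expect_equal(back@logEvery, 10)
})
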