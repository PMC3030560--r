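#' @include AllClasses.R AllGenerics.R timetree.R
NULL

#' Tip substitution rates
#'
#' The rate of the terminal branch leading to each taxon, as displayed next
#' to the tips of a rate-annotated time tree.
#'
#' @param t A [TimeTree-class] with annotated terminal branches.
#' @param taxa Taxa to extract (default: all tips).
#' @return Data frame with columns `taxon` and `tip_rate`
#'   (substitutions/site/my).
#' @export
tipRates <- function(t, taxa = taxonLabels(t)) {
  stopifnot(is(t, "TimeTree"))
  phy <- t@phylo
  missing <- setdiff(taxa, phy$tip.label)
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  tipNum <- match(taxa, phy$tip.label)
  eIdx <- match(tipNum, phy$edge[, 2])
  r <- t@rates[eIdx]
  if (anyNA(r))
    stop("unannotated terminal branch for: ",
         paste(taxa[is.na(r)], collapse = ", "))
  data.frame(taxon = taxa, tip_rate = r, stringsAsFactors = FALSE)
}

#' Path-averaged substitution rates
#'
#' For each taxon, the unweighted arithmetic mean of the branch rates on the
#' path from the ancestral node connecting the tested taxa down to (and
#' including) the terminal branch. This damps the inflation of rate
#' estimates on terminal branches caused by transient polymorphism. The
#' branch above the ancestor is excluded by default (`includeStem = TRUE`
#' adds it for sensitivity analysis); `timeWeighted = TRUE` weights each
#' branch's rate by its duration instead.
#'
#' @param t A [TimeTree-class]; every branch on each path must be annotated.
#' @param taxa Taxa whose averaged rates are wanted.
#' @param ancestor Taxon set whose MRCA is the ancestral node (default: the
#'   MRCA of `taxa`), or `"root"`.
#' @param includeStem Also average over the branch above the ancestor.
#' @param timeWeighted Duration-weighted instead of unweighted mean.
#' @return Data frame with columns `taxon` and `averaged_rate`.
#' @export
averagedRates <- function(t, taxa = taxonLabels(t), ancestor = taxa,
                          includeStem = FALSE, timeWeighted = FALSE) {
  stopifnot(is(t, "TimeTree"))
  phy <- t@phylo
  anc <- if (length(ancestor) == 1 && identical(ancestor, "root"))
    rootNode(t) else if (length(ancestor) == 1)
      stop("ancestor must be >= 2 taxa or 'root'") else mrcaNode(t, ancestor)
  dur <- branchDurations(t)
  stemEdge <- match(anc, phy$edge[, 2])  # NA when ancestor is the root
  out <- vapply(taxa, function(tx) {
    tip <- match(tx, phy$tip.label)
    if (is.na(tip)) stop("taxon not in tree: ", tx)
    path <- integer(0)
    node <- tip
    while (node != anc) {
      e <- match(node, phy$edge[, 2])
      if (is.na(e))
        stop("ancestor is not ancestral to taxon ", tx)
      path <- c(path, e)
      node <- phy$edge[e, 1]
    }
    if (includeStem && !is.na(stemEdge)) path <- c(path, stemEdge)
    r <- t@rates[path]
    if (anyNA(r)) stop("unannotated branch on the path to ", tx)
    if (timeWeighted) sum(r * dur[path]) / sum(dur[path]) else mean(r)
  }, numeric(1))
  data.frame(taxon = taxa, averaged_rate = as.numeric(out),
             stringsAsFactors = FALSE)
}

setMethod("show", "RankSumResult", function(object) {
  cat("Mann-Whitney rank-sum test (", object@method, ")\n", sep = "")
  cat("  n1 =", object@n1, " n2 =", object@n2,
      " U =", format(object@U), " p =", format(object@pValue, digits = 4),
      "\n")
})

#' Mann-Whitney U / Wilcoxon rank-sum test
#'
#' `U` counts pairs `(i, j)` with `x_i > y_j`, ties counting one half.
#' Exact mode enumerates all `choose(n1 + n2, n1)` group labelings of the
#' pooled data (tie-free samples only) and reports the two-sided p as twice
#' the smaller tail, capped at one. Normal mode uses mean `n1 n2 / 2`,
#' variance with the mid-rank tie correction and a 0.5 continuity
#' correction toward the mean, matching the convention of
#' `stats::wilcox.test(correct = TRUE)`. `"auto"` picks exact for tie-free
#' samples with `n1 + n2 <= 20`.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A [RankSumResult-class].
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6), mode = "exact")
#' @export
rankSumTest <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  hasTies <- anyDuplicated(pooled) > 0
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  if (mode == "auto")
    mode <- if (!hasTies && n1 + n2 <= 20) "exact" else "normal"
  if (mode == "exact") {
    if (hasTies) stop("exact mode is unsupported with ties")
    if (n1 + n2 > 24) stop("exact enumeration limited to n1 + n2 <= 24")
    labelings <- utils::combn(n1 + n2, n1)
    Us <- apply(labelings, 2, function(idx) {
      xx <- pooled[idx]; yy <- pooled[-idx]
      sum(outer(xx, yy, ">"))
    })
    pLow <- mean(Us <= U)
    pHigh <- mean(Us >= U)
    p <- min(1, 2 * min(pLow, pHigh))
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tieCorr)
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- U - n1 * n2 / 2
      z <- sign(z) * max(0, abs(z) - 0.5)  # continuity correction
      p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
      p <- min(1, p)
    }
    method <- "normal-approximation"
  }
  new("RankSumResult", U = U, pValue = p, method = method,
      n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Collapse a group of points into its arithmetic mean
#'
#' Replaces all rows of `points` in the named group by a single row whose
#' numeric values are the per-column arithmetic means of the members
#' (missing values excluded per column). Used to collapse the six beaver
#' samples into one data point before regressions, avoiding unbalanced
#' data.
#'
#' @param points Data frame with columns `taxon`, `group`, and numeric
#'   columns (rates, traits).
#' @param groupLabel The group to collapse (must be non-empty).
#' @return Data frame with the group replaced by one row named
#'   `<groupLabel>_mean`.
#' @export
collapseGroup <- function(points, groupLabel) {
  stopifnot(is.data.frame(points), "group" %in% names(points))
  inGroup <- points$group == groupLabel
  if (!any(inGroup)) stop("empty group: ", groupLabel)
  if (sum(inGroup) == 1) return(points)
  numCols <- names(points)[vapply(points, is.numeric, logical(1))]
  rep <- points[which(inGroup)[1], , drop = FALSE]
  rep$taxon <- paste0(groupLabel, "_mean")
  for (col in numCols) {
    v <- mean(points[[col]][inGroup], na.rm = TRUE)
    rep[[col]] <- if (is.nan(v)) NA_real_ else v  # all-missing trait stays NA
  }
  out <- rbind(points[!inGroup, , drop = FALSE], rep)
  rownames(out) <- NULL
  out
}

setMethod("show", "RegressionResult", function(object) {
  cat("Linear regression (OLS, n = ", object@n, ")\n", sep = "")
  cat("  slope =", format(object@slope, digits = 5),
      " intercept =", format(object@intercept, digits = 5), "\n")
  cat("  R^2 =", format(object@rSquared, digits = 4),
      " p =", format(object@pValue, digits = 4), "\n")
})

#' Ordinary least-squares regression of rates on a trait
#'
#' Pairs with a missing value in either variable are dropped; the two-sided
#' p-value is the t test on the slope with `n - 2` degrees of freedom.
#' Values are used untransformed (set `logY = TRUE` to regress log rates,
#' an option from the comparative literature that is flagged, never applied
#' silently).
#'
#' @param x Predictor values (e.g. maximum lifespan in years).
#' @param y Response values (e.g. substitution rates).
#' @param logY Regress `log(y)` instead of `y`.
#' @return A [RegressionResult-class].
#' @examples
#' linearRegression(c(1, 2, 3), c(1, 3, 4))
#' @export
linearRegression <- function(x, y, logY = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("regression needs >= 3 complete pairs")
  if (stats::var(x) == 0) stop("zero variance in predictor")
  if (logY) y <- log(y)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # "perfect fit" warning is benign
  pv <- if (sm$sigma == 0) 0 else sm$coefficients["x", "Pr(>|t|)"]
  new("RegressionResult",
      slope = unname(stats::coef(fit)["x"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      rSquared = sm$r.squared,
      pValue = pv,
      n = as.integer(length(x)))
}

#' Clade rate comparisons and life-history regressions
#'
#' Reproduces the two report shapes of a rate-comparison analysis: (i) for
#' each named comparison clade, a Mann-Whitney test of the focal group's
#' tip and path-averaged rates against the rest of that clade; (ii) OLS
#' regressions of tip and averaged rates on each trait column, with the
#' focal group collapsed to one point.
#'
#' @param t A rate-annotated [TimeTree-class].
#' @param focal Character vector of focal taxa (e.g. the slow clade).
#' @param comparisons Named list of taxon sets, each containing `focal`;
#'   the focal group is tested against the other members of each set, and
#'   averaged rates use that set's MRCA as the ancestral node.
#' @param traits Optional data frame with `taxon` and numeric trait columns.
#' @param collapseFocal Collapse the focal group to one point in the
#'   regressions.
#' @param mode Rank-sum p-value mode passed to [rankSumTest()].
#' @return List with data frames `tests` (one row per comparison x rate
#'   type: `U`, `p_value`, group sizes) and `regressions` (one row per
#'   trait x rate type: slope, `r_squared`, `p_value`, n), the latter
#'   `NULL` without traits.
#' @export
rateComparisonReport <- function(t, focal, comparisons, traits = NULL,
                                 collapseFocal = TRUE,
                                 mode = "normal") {
  stopifnot(is(t, "TimeTree"), length(focal) > 0)
  tests <- list()
  for (nm in names(comparisons)) {
    set <- comparisons[[nm]]
    rest <- setdiff(set, focal)
    if (length(rest) == 0) stop("comparison '", nm, "' has no non-focal taxa")
    tipTab <- tipRates(t, set)
    avgTab <- averagedRates(t, taxa = set, ancestor = set)
    for (type in c("tip", "averaged")) {
      tab <- if (type == "tip") tipTab else avgTab
      v <- stats::setNames(tab[[2]], tab$taxon)
      res <- rankSumTest(v[focal], v[rest], mode = mode)
      tests[[length(tests) + 1]] <-
        data.frame(comparison = nm, rate_type = type,
                   U = res@U, p_value = res@pValue, method = res@method,
                   n_focal = res@n1, n_rest = res@n2,
                   stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)

  regressions <- NULL
  if (!is.null(traits)) {
    allTaxa <- taxonLabels(t)
    tipTab <- tipRates(t, allTaxa)
    avgTab <- averagedRates(t, taxa = allTaxa, ancestor = "root")
    pts <- merge(merge(tipTab, avgTab, by = "taxon"), traits, by = "taxon",
                 all.x = TRUE)
    pts$group <- ifelse(pts$taxon %in% focal, "focal", "other")
    if (collapseFocal) pts <- collapseGroup(pts, "focal")
    traitCols <- setdiff(names(traits), "taxon")
    rows <- list()
    for (tr in traitCols) {
      for (type in c("tip", "averaged")) {
        yv <- if (type == "tip") pts$tip_rate else pts$averaged_rate
        res <- linearRegression(pts[[tr]], yv)
        rows[[length(rows) + 1]] <-
          data.frame(trait = tr, rate_type = type,
                     slope = res@slope, intercept = res@intercept,
                     r_squared = res@rSquared, p_value = res@pValue,
                     n = res@n, stringsAsFactors = FALSE)
      }
    }
    regressions <- do.call(rbind, rows)
  }
  list(tests = tests, regressions = regressions)
}
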