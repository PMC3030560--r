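#' @include AllClasses.R AllGenerics.R timetree.R
NULL

#' Construct a ClockTrace
#'
#' @param samples Data frame of logged scalars including a strictly
#'   increasing `generation` column.
#' @param logEvery Logging interval in generations.
#' @param acceptance Optional named acceptance rates per move type.
#' @return A [ClockTrace-class].
#' @export
clockTrace <- function(samples, logEvery = 1, acceptance = numeric(0)) {
  new("ClockTrace", samples = samples, logEvery = as.numeric(logEvery),
      acceptance = acceptance)
}

#' @rdname traceSamples
#' @export
setMethod("traceSamples", "ClockTrace", function(x) x@samples)

setMethod("show", "ClockTrace", function(object) {
  s <- object@samples
  cat("ClockTrace:", nrow(s), "samples x", ncol(s), "columns",
      "(logged every", object@logEvery, "generations)\n")
  if (all(c("posterior", "likelihood") %in% names(s)))
    cat("  final posterior:", format(s$posterior[nrow(s)], digits = 8), "\n")
  if (length(object@acceptance) > 0) {
    cat("  acceptance rates:\n")
    for (nm in names(object@acceptance))
      cat("    ", nm, ": ", format(object@acceptance[[nm]], digits = 3),
          "\n", sep = "")
  }
})

#' Write / read a trace as TSV
#'
#' One row per sample, one column per logged quantity.
#'
#' @param x A [ClockTrace-class].
#' @param path File path.
#' @return `writeTrace`: `path` invisibly; `readTrace`: a
#'   [ClockTrace-class].
#' @export
writeTrace <- function(x, path) {
  stopifnot(is(x, "ClockTrace"))
  utils::write.table(x@samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  s <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  le <- if (nrow(s) > 1) s$generation[2] - s$generation[1] else 1
  clockTrace(s, logEvery = le)
}

#' Combine traces after per-trace burn-in removal
#'
#' Removes the first `ceiling(burninFraction * rows)` rows from each input
#' trace separately (mirroring manual log combining where automatic burn-in
#' removal is unreliable), then concatenates and re-indexes generations at
#' the first trace's logging interval.
#'
#' @param traces List of [ClockTrace-class] objects with identical columns.
#' @param burninFraction Fraction in `[0, 1)` discarded per trace; default
#'   0.10.
#' @return A [ClockTrace-class].
#' @examples
#' tr <- clockTrace(data.frame(generation = 0:9, x = rnorm(10)))
#' nrow(traceSamples(combineTraces(list(tr, tr), 0.1)))
#' @export
combineTraces <- function(traces, burninFraction = 0.10) {
  if (is(traces, "ClockTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  if (burninFraction < 0 || burninFraction >= 1)
    stop("burninFraction must lie in [0, 1)")
  cols <- lapply(traces, function(tr) names(tr@samples))
  for (i in seq_along(cols))
    if (!identical(cols[[i]], cols[[1]]))
      stop("trace ", i, " has a different column set")
  kept <- lapply(traces, function(tr) {
    s <- tr@samples
    drop <- ceiling(burninFraction * nrow(s))
    if (drop >= nrow(s)) stop("burn-in removes an entire trace")
    s[(drop + 1):nrow(s), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  le <- traces[[1]]@logEvery
  out$generation <- seq(0, by = le, length.out = nrow(out))
  rownames(out) <- NULL
  clockTrace(out, logEvery = le)
}

#' Effective sample size of an autocorrelated series
#'
#' `n / (1 + 2 * sum(rho_k))` with empirical autocorrelations summed until
#' the first non-positive estimate, capped at `n` — the standard
#' initial-positive-sequence estimator used for MCMC trace diagnostics.
#'
#' @param series Numeric vector of length >= 10.
#' @return The effective sample size.
#' @export
effectiveSampleSize <- function(series) {
  n <- length(series)
  if (n < 10) stop("series too short for an ESS estimate (need >= 10)")
  if (stats::var(series) == 0)
    stop("constant series: autocorrelation undefined")
  ac <- stats::acf(series, lag.max = n - 1, plot = FALSE,
                   demean = TRUE)$acf[-1]
  sumRho <- 0
  for (rho in ac) {
    if (rho <= 0) break
    sumRho <- sumRho + rho
  }
  min(n, n / (1 + 2 * sumRho))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param mass Probability mass in `(0, 1)`; default 0.95.
#' @return Numeric `c(low, high)`.
#' @examples
#' hpdInterval(1:100, 0.95)
#' @export
hpdInterval <- function(samples, mass = 0.95) {
  if (length(samples) < 2) stop("need >= 2 samples for an HPD interval")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Summarize a clade's age from a trace
#'
#' Arithmetic mean, median and 95% highest-posterior-density interval of a
#' clade's MRCA age over the (post burn-in) samples — the shape in which
#' divergence dates are reported (e.g. "mean 8, median 7.6, HPD 3.7-13
#' my").
#'
#' @param trace A [ClockTrace-class].
#' @param clade Taxon set (or `"root"`), resolved against `topology`; or
#'   directly the name of an age column such as `"age_25"`.
#' @param topology The [TimeTree-class] the trace was sampled on (needed
#'   unless `clade` is a column name).
#' @param mass HPD mass, default 0.95.
#' @return List with `mean`, `median`, `hpd` (length-2 numeric) and `n`.
#' @export
summarizeCladeAge <- function(trace, clade, topology = NULL, mass = 0.95) {
  stopifnot(is(trace, "ClockTrace"))
  s <- trace@samples
  col <- if (length(clade) == 1 &&
             (clade %in% names(s) || is.null(topology))) clade else {
    if (is.null(topology))
      stop("topology needed to resolve clade ", paste(clade, collapse = ","))
    paste0("age_", mrcaNode(topology, clade))
  }
  if (!col %in% names(s))
    stop("unknown clade/column in trace: ", col)
  v <- s[[col]]
  list(mean = mean(v), median = stats::median(v),
       hpd = hpdInterval(v, mass), n = length(v))
}

#' Annotate a topology with posterior mean ages and branch rates
#'
#' Sets every internal node age to its posterior mean and annotates every
#' branch with the posterior mean of its rate column, yielding the tree one
#' would display with rates on the branches.
#'
#' @param trace A [ClockTrace-class] with `age_<node>` and `rate_<child>`
#'   columns.
#' @param topology The [TimeTree-class] the trace was sampled on.
#' @return A [TimeTree-class] with posterior mean ages and rates.
#' @export
annotatePosteriorRates <- function(trace, topology) {
  stopifnot(is(trace, "ClockTrace"), is(topology, "TimeTree"))
  s <- trace@samples
  phy <- topology@phylo
  ntip <- ape::Ntip(phy)
  ages <- topology@ages
  for (node in (ntip + 1):(ntip + phy$Nnode)) {
    col <- paste0("age_", node)
    if (!col %in% names(s)) stop("missing age column: ", col)
    ages[node] <- mean(s[[col]])
  }
  rates <- numeric(nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    col <- paste0("rate_", phy$edge[e, 2])
    if (!col %in% names(s)) stop("missing branch rate column: ", col)
    rates[e] <- mean(s[[col]])
  }
  timeTree(phy, ages = ages, rates = rates)
}
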