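#' @include AllClasses.R
NULL

#' Taxon labels of an object
#' @param x An [Alignment-class] or [TimeTree-class].
#' @return Character vector of taxon labels in the object's order.
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' Number of taxa
#' @param x An [Alignment-class] or [TimeTree-class].
#' @return Integer count of taxa.
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' Alignment length in columns (bp, gaps included)
#' @param x An [Alignment-class].
#' @return Integer column count.
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' Node ages of a time tree
#' @param x A [TimeTree-class].
#' @return Numeric vector of ages (my) indexed by ape node number.
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' Per-branch substitution rates
#' @param x A [TimeTree-class].
#' @return Numeric vector aligned with `asPhylo(x)$edge` rows; `NA` where a
#'   branch carries no rate annotation.
#' @export
setGeneric("branchRates", function(x) standardGeneric("branchRates"))

#' Replace per-branch substitution rates
#' @param x A [TimeTree-class].
#' @param value Numeric vector, one entry per edge.
#' @return The modified [TimeTree-class].
#' @export
setGeneric("branchRates<-", function(x, value) standardGeneric("branchRates<-"))

#' Per-branch durations (parent age minus child age)
#' @param x A [TimeTree-class].
#' @return Numeric vector of durations (my) aligned with edge rows.
#' @export
setGeneric("branchDurations",
           function(x) standardGeneric("branchDurations"))

#' Convert to an ape phylo object
#' @param x A [TimeTree-class].
#' @return A `phylo` with edge lengths equal to branch durations.
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))

#' Trace samples as a data frame
#' @param x A [ClockTrace-class].
#' @return Data frame of logged values, one row per sample.
#' @export
setGeneric("traceSamples", function(x) standardGeneric("traceSamples"))
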