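#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an Alignment from sequences
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   taxa-by-columns character matrix with row names.
#' @return An [Alignment-class]. Lowercase input is normalized to uppercase.
#' @examples
#' a <- alignment(c(tax1 = "ACGT", tax2 = "AC-T"))
#' alignmentLength(a)
#' @export
alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1)
      stop("malformed alignment: rows have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    if (length(seqs) == 1 && lens == 0) mat <- matrix("", 1, 0)
    rownames(mat) <- names(seqs)
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  new("Alignment", mat = mat)
}

#' @describeIn alignment Character matrix of states (taxa x columns).
#' @param x An [Alignment-class].
#' @export
alignmentMatrix <- function(x) x@mat

#' @rdname taxonLabels
#' @export
setMethod("taxonLabels", "Alignment", function(x) rownames(x@mat))

#' @rdname nTaxa
#' @export
setMethod("nTaxa", "Alignment", function(x) nrow(x@mat))

#' @rdname alignmentLength
#' @export
setMethod("alignmentLength", "Alignment", function(x) ncol(x@mat))

setMethod("show", "Alignment", function(object) {
  cat("Alignment:", nrow(object@mat), "taxa x", ncol(object@mat),
      "columns\n")
  if (nrow(object@mat) > 0) {
    shown <- utils::head(rownames(object@mat), 5)
    cat("  taxa:", paste(shown, collapse = ", "),
        if (nrow(object@mat) > 5) "..." else "", "\n")
  }
})

#' Read a multiple sequence alignment
#'
#' Reads FASTA (via Biostrings) or NEXUS DATA blocks (via ape), preserving
#' input taxon order and normalizing to uppercase.
#'
#' @param path File to read.
#' @param format `"fasta"` or `"nexus"`; the default guesses from the file
#'   extension (`.nex`/`.nexus` is NEXUS, anything else FASTA).
#' @return An [Alignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), f)
#' readAlignment(f)
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1)
      stop("malformed alignment: unequal sequence lengths in ", path)
    alignment(seqs)
  } else {
    recs <- ape::read.nexus.data(path)
    alignment(vapply(recs, paste, character(1), collapse = ""))
  }
}

#' Write a multiple sequence alignment
#'
#' @param x An [Alignment-class].
#' @param path Output file.
#' @param format `"fasta"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(x, path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  stopifnot(is(x, "Alignment"))
  seqs <- apply(x@mat, 1, paste, collapse = "")
  if (ncol(x@mat) == 0)
    seqs <- stats::setNames(rep("", nrow(x@mat)), rownames(x@mat))
  if (format == "fasta") {
    ss <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(ss, path)
  } else {
    ape::write.nexus.data(strsplit(seqs, ""), path, interleaved = FALSE)
  }
  invisible(path)
}

#' Remove a contiguous block of alignment columns
#'
#' Drops the 1-based inclusive column interval `[start, end]` — e.g. a
#' poorly aligned control-region block — leaving taxa unchanged.
#'
#' @param x An [Alignment-class].
#' @param start,end 1-based inclusive column bounds, `1 <= start <= end <=
#'   alignmentLength(x)`.
#' @return An [Alignment-class] with `end - start + 1` fewer columns.
#' @examples
#' a <- alignment(c(t1 = "AAACGT", t2 = "AAACGA"))
#' alignmentLength(removeColumns(a, 1, 3))
#' @export
removeColumns <- function(x, start, end) {
  stopifnot(is(x, "Alignment"))
  L <- ncol(x@mat)
  if (start < 1 || end > L || start > end)
    stop("column block [", start, ", ", end, "] out of range for alignment of ",
         L, " columns")
  new("Alignment", mat = x@mat[, -(start:end), drop = FALSE])
}

#' Read a life-history trait table
#'
#' Tab-separated file with a header; the first column names the taxon, the
#' remaining columns are numeric traits (canonically `lifespan` in years,
#' `body_mass` in grams, `sexual_maturity` in years). Empty cells and `NA`
#' are recorded as missing.
#'
#' @param path TSV file.
#' @return Data frame with a `taxon` column and numeric trait columns;
#'   strictly positive where present.
#' @export
readTraitTable <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  names(df)[1] <- "taxon"
  df$taxon <- as.character(df$taxon)
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon rows: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  for (col in names(df)[-1]) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(conv)))
        stop("non-numeric value in trait column '", col, "'")
      v <- conv
    }
    if (any(!is.na(v) & v <= 0))
      stop("trait '", col, "' must be strictly positive where present")
    df[[col]] <- as.numeric(v)
  }
  df
}

#' Write a life-history trait table
#'
#' @param traits Data frame as returned by [readTraitTable()] or
#'   [simulateTraits()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
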