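#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TimeTree
#'
#' @param phy A rooted binary `phylo`. If `ages` is `NULL`, node ages are
#'   derived from `phy$edge.length` by placing the deepest tip at age 0.
#' @param ages Optional numeric vector of node ages (my) indexed by ape node
#'   number.
#' @param rates Optional per-edge substitution rates (substitutions/site/my),
#'   aligned with `phy$edge` rows; `NA` = unannotated.
#' @param annotations Optional per-edge list of named character vectors of
#'   extra branch annotations.
#' @return A [TimeTree-class].
#' @examples
#' tt <- timeTree(ape::read.tree(text = "(A:1,B:1);"))
#' nodeAges(tt)
#' @export
timeTree <- function(phy, ages = NULL, rates = NULL, annotations = NULL) {
  stopifnot(inherits(phy, "phylo"))
  nEdge <- nrow(phy$edge)
  nn <- ape::Ntip(phy) + phy$Nnode
  if (is.null(ages)) {
    if (is.null(phy$edge.length))
      stop("phylo has no edge lengths and no ages were given")
    if (any(phy$edge.length < 0))
      stop("negative branch length in input tree")
    depth <- ape::node.depth.edgelength(phy)
    ages <- max(depth) - depth
    ages[abs(ages) < 1e-12] <- 0
  }
  if (is.null(rates)) rates <- rep(NA_real_, nEdge)
  if (is.null(annotations))
    annotations <- rep(list(character(0)), nEdge)
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  new("TimeTree", phylo = phy, ages = as.numeric(ages),
      rates = as.numeric(rates), annotations = annotations)
}

#' @rdname taxonLabels
#' @export
setMethod("taxonLabels", "TimeTree", function(x) x@phylo$tip.label)

#' @rdname nTaxa
#' @export
setMethod("nTaxa", "TimeTree", function(x) ape::Ntip(x@phylo))

#' @rdname nodeAges
#' @export
setMethod("nodeAges", "TimeTree", function(x) x@ages)

#' @rdname branchRates
#' @export
setMethod("branchRates", "TimeTree", function(x) x@rates)

#' @rdname branchRates-set
#' @export
setMethod("branchRates<-", "TimeTree", function(x, value) {
  x@rates <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname branchDurations
#' @export
setMethod("branchDurations", "TimeTree", function(x) {
  x@ages[x@phylo$edge[, 1]] - x@ages[x@phylo$edge[, 2]]
})

#' @rdname asPhylo
#' @export
setMethod("asPhylo", "TimeTree", function(x) {
  phy <- x@phylo
  phy$edge.length <- branchDurations(x)
  phy
})

setMethod("show", "TimeTree", function(object) {
  phy <- object@phylo
  cat("TimeTree:", ape::Ntip(phy), "tips,", phy$Nnode, "internal nodes\n")
  cat("  root age:", format(rootAge(object), digits = 6), "my\n")
  nr <- sum(!is.na(object@rates))
  cat("  branch rates:", if (nr == 0) "none" else
    paste0(nr, "/", nrow(phy$edge), " annotated"), "\n")
})

#' Root node number and root age
#'
#' @param x A [TimeTree-class].
#' @return `rootNode()` the ape node number of the root; `rootAge()` its age
#'   in my.
#' @export
rootNode <- function(x) ape::Ntip(x@phylo) + 1L

#' @rdname rootNode
#' @export
rootAge <- function(x) x@ages[rootNode(x)]

#' MRCA node of a taxon set
#'
#' @param x A [TimeTree-class].
#' @param taxa Character vector of tip labels (length >= 2), or `"root"`.
#' @return Ape node number of the most recent common ancestor.
#' @export
mrcaNode <- function(x, taxa) {
  phy <- x@phylo
  if (length(taxa) == 1 && identical(taxa, "root")) return(rootNode(x))
  missing <- setdiff(taxa, phy$tip.label)
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(taxa) < 2) stop("an MRCA needs >= 2 taxa")
  ape::getMRCA(phy, taxa)
}

#' Tip labels descending from a node
#' @param x A [TimeTree-class].
#' @param node Ape node number.
#' @return Character vector of tip labels in the subtree rooted at `node`.
#' @export
cladeTips <- function(x, node) {
  phy <- x@phylo
  if (node <= ape::Ntip(phy)) return(phy$tip.label[node])
  ape::extract.clade(phy, node)$tip.label
}

## Edge indices (rows of phylo$edge) whose child node lies inside the clade
## rooted at `node`, i.e. the branches of the crown group (stem excluded).
.cladeEdgeRows <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  tips <- if (node <= ntip) node else
    which(phy$tip.label %in% ape::extract.clade(phy, node)$tip.label)
  desc <- integer(0)
  stack <- node
  children <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack) > 0) {
    cur <- stack[[1]]; stack <- stack[-1]
    kids <- children[[as.character(cur)]]
    desc <- c(desc, kids)
    stack <- c(stack, kids[kids > ntip])
  }
  which(phy$edge[, 2] %in% desc)
}

## ---- Annotated Newick I/O ---------------------------------------------

## Parse one [&key=value,...] comment into a named character vector.
.parseAnnotation <- function(txt) {
  body <- sub("^\\[&?", "", sub("\\]$", "", txt))
  if (nchar(body) == 0) return(character(0))
  parts <- strsplit(body, ",(?![^{]*\\})", perl = TRUE)[[1]]
  kv <- regmatches(parts, regexpr("=", parts), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) if (length(p) > 1) p[2] else "", character(1))
  stats::setNames(vals, keys)
}

## Recursive-descent parser for rooted Newick with optional [&key=value]
## branch comments (BEAST dialect: after the node label/closing paren and/or
## after the branch length). Returns a TimeTree. Hand-written because no
## installed parser retains these comments.
.parseNewick <- function(text) {
  s <- gsub("[\r\n\t ]", "", text)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos > n) "" else chars[pos]
  .STRUCTURAL <- c("[", "]", ":", ",", "(", ")", ";")
  .NUMCHARS <- c(as.character(0:9), "e", "E", ".", "+", "-")
  nodes <- list()   # each: list(label, children, length, ann)
  newNode <- function() {
    nodes[[length(nodes) + 1L]] <<- list(label = "", children = integer(0),
                                         length = NA_real_, ann = character(0))
    length(nodes)
  }
  readWhile <- function(allowed = NULL, notIn = NULL) {
    start <- pos
    while (pos <= n &&
           (if (is.null(allowed)) !(chars[pos] %in% notIn)
            else chars[pos] %in% allowed))
      pos <<- pos + 1L
    if (pos == start) "" else paste(chars[start:(pos - 1L)], collapse = "")
  }
  readComment <- function() {
    stopifnot(peek() == "[")
    start <- pos
    depth <- 0L
    repeat {
      ch <- peek()
      if (ch == "") stop("unterminated [ comment in Newick input")
      if (ch == "[") depth <- depth + 1L
      if (ch == "]") depth <- depth - 1L
      pos <<- pos + 1L
      if (depth == 0L) break
    }
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parseClade <- function() {
    id <- newNode()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        child <- parseClade()
        nodes[[id]]$children <<- c(nodes[[id]]$children, child)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick: expected ',' or ')' at position ", pos)
      }
    }
    nodes[[id]]$label <<- readWhile(notIn = .STRUCTURAL)
    while (peek() == "[") {
      ann <- .parseAnnotation(readComment())
      nodes[[id]]$ann <<- c(nodes[[id]]$ann, ann)
    }
    if (peek() == ":") {
      pos <<- pos + 1L
      while (peek() == "[") {
        ann <- .parseAnnotation(readComment())
        nodes[[id]]$ann <<- c(nodes[[id]]$ann, ann)
      }
      numtxt <- readWhile(allowed = .NUMCHARS)
      len <- suppressWarnings(as.numeric(numtxt))
      if (is.na(len)) stop("malformed branch length '", numtxt, "'")
      nodes[[id]]$length <<- len
      while (peek() == "[") {
        ann <- .parseAnnotation(readComment())
        nodes[[id]]$ann <<- c(nodes[[id]]$ann, ann)
      }
    }
    id
  }
  root <- parseClade()
  if (peek() != ";") stop("malformed Newick: expected ';' at position ", pos)

  isTip <- vapply(nodes, function(nd) length(nd$children) == 0, logical(1))
  for (nd in nodes[!isTip])
    if (length(nd$children) != 2)
      stop("unsupported tree: polytomy or unary node (binary rooted required)")
  ntip <- sum(isTip)
  if (ntip < 2) stop("unsupported tree: fewer than 2 tips")
  num <- integer(length(nodes))
  num[isTip] <- seq_len(ntip)
  ## internal nodes numbered in the order encountered = preorder, root first
  num[!isTip] <- ntip + seq_len(sum(!isTip))
  edge <- matrix(0L, length(nodes) - 1L, 2L)
  lens <- numeric(nrow(edge))
  anns <- vector("list", nrow(edge))
  k <- 0L
  for (i in seq_along(nodes)) {
    for (ch in nodes[[i]]$children) {
      k <- k + 1L
      edge[k, ] <- c(num[i], num[ch])
      len <- nodes[[ch]]$length
      if (is.na(len)) stop("branch without length in Newick input")
      if (len < 0) stop("negative branch length in input tree")
      lens[k] <- len
      anns[[k]] <- nodes[[ch]]$ann
    }
  }
  ## reorder edges so parents appear in ape's expected cladewise-ish order
  ord <- order(edge[, 1], edge[, 2])
  edge <- edge[ord, , drop = FALSE]; lens <- lens[ord]; anns <- anns[ord]
  phy <- structure(list(edge = edge, edge.length = lens,
                        tip.label = vapply(nodes[isTip], `[[`, character(1),
                                           "label"),
                        Nnode = sum(!isTip)), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  rates <- rep(NA_real_, nrow(edge))
  extras <- vector("list", nrow(edge))
  ## recompute annotation alignment after reorder: match on (parent, child)
  key0 <- paste(edge[, 1], edge[, 2])
  key1 <- paste(phy$edge[, 1], phy$edge[, 2])
  map <- match(key1, key0)
  lens <- lens[map]; anns <- anns[map]
  phy$edge.length <- lens
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    if ("rate" %in% names(a)) {
      rates[i] <- as.numeric(a[["rate"]])
      a <- a[names(a) != "rate"]
    }
    extras[[i]] <- a
  }
  timeTree(phy, rates = rates, annotations = extras)
}

#' Read a rooted time tree from annotated Newick
#'
#' Accepts standard Newick with branch lengths plus optional BEAST-style
#' `[&key=value,...]` branch comments. A `rate` key becomes the branch's
#' substitution rate; all other keys are preserved verbatim and round-trip
#' through [writeTimeTree()]. Node ages are reconstructed by placing the
#' deepest tip at age 0.
#'
#' @param path File containing one Newick tree (a bare NEXUS TREES block with
#'   a single tree is also accepted).
#' @return A [TimeTree-class].
#' @export
readTimeTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(txt, regexpr("\\([^;]*;", txt))
  if (length(m) == 0) stop("no Newick tree found in ", path)
  .parseNewick(m)
}

#' @rdname readTimeTree
#' @param text A Newick string (alternative to reading from a file).
#' @export
parseTimeTree <- function(text) .parseNewick(text)

## Serialize one annotation vector (plus rate) to [&...] or "".
.formatAnnotation <- function(rate, extra) {
  parts <- character(0)
  if (!is.na(rate)) parts <- paste0("rate=", format(rate, digits = 15))
  if (length(extra) > 0)
    parts <- c(parts, paste0(names(extra), "=", extra))
  if (length(parts) == 0) return("")
  paste0("[&", paste(parts, collapse = ","), "]")
}

#' Write a time tree as annotated Newick
#'
#' Branch lengths are durations in my; branch rates and any preserved
#' annotations are written as `[&key=value]` comments after the node label.
#'
#' @param x A [TimeTree-class].
#' @param path Output file; `NULL` returns the Newick string instead.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to a file.
#' @export
writeTimeTree <- function(x, path = NULL, digits = 15) {
  stopifnot(is(x, "TimeTree"))
  phy <- x@phylo
  ntip <- ape::Ntip(phy)
  dur <- branchDurations(x)
  edgeOfChild <- match(seq_len(ntip + phy$Nnode), phy$edge[, 2])
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  fmt <- function(node) {
    eIdx <- edgeOfChild[node]
    lab <- if (node <= ntip) phy$tip.label[node] else ""
    core <- if (node <= ntip) lab else {
      kids <- children[[as.character(node)]]
      paste0("(", paste(vapply(phy$edge[kids, 2], fmt, character(1)),
                        collapse = ","), ")")
    }
    if (is.na(eIdx)) return(core)  # root: no branch above
    ann <- .formatAnnotation(x@rates[eIdx], x@annotations[[eIdx]])
    paste0(core, ann, ":", format(dur[eIdx], digits = digits))
  }
  nwk <- paste0(fmt(ntip + 1L), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
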