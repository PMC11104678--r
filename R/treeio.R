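#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Internal node labels
#' (bootstrap values, simulation frequencies, ...) are preserved as node
#' annotations, never interpreted as taxon names. Missing branch lengths are
#' kept as `NA`, not silently coerced to zero; a tree with no lengths at all
#' has a `NULL` `edge.length`.
#'
#' @param text A single Newick statement terminated by `;`.
#' @return An object of class `phylo`.
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text))
    stop("empty Newick string")
  if (!grepl(";\\s*$", text))
    stop("Newick statement must end with ';'")
  .checkBalanced(text)
  # single-label degenerate tree "A;" (ape cannot represent a 0-edge tree)
  if (!grepl("[(),]", text)) {
    lab <- sub(";\\s*$", "", text)
    lab <- sub(":.*$", "", lab)
    if (!nzchar(lab)) stop("empty tip label in Newick input")
    phy <- structure(
      list(edge = matrix(integer(0), 0L, 2L), tip.label = lab, Nnode = 0L),
      class = "phylo", order = "cladewise", singleTip = TRUE)
    return(phy)
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w)))
  if (is.null(phy))
    stop("Newick parse error: input could not be read as a tree")
  .validateTipLabels(phy$tip.label)
  if (!is.null(phy$edge.length)) {
    phy$edge.length[is.nan(phy$edge.length)] <- NA_real_
    bad <- which(!is.na(phy$edge.length) & phy$edge.length < 0)
    if (length(bad))
      stop("negative branch length on edge ", bad[1L])
    if (all(is.na(phy$edge.length))) phy$edge.length <- NULL
  }
  phy
}

.checkBalanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses: unmatched ')' at position ", i)
    }
  }
  if (depth > 0L)
    stop("unbalanced parentheses: ", depth, " unclosed '(' in Newick input")
  invisible(TRUE)
}

.validateTipLabels <- function(labs) {
  if (any(!nzchar(labs)))
    stop("empty tip label in Newick input")
  dup <- labs[duplicated(labs)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  invisible(TRUE)
}

#' Read one or several Newick trees from a file
#'
#' @param file Path to a file with one Newick statement per line (blank lines
#'   ignored).
#' @return A list of `phylo` objects (length one for a single-tree file).
#' @export
readNewickFile <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no trees in ", file)
  lapply(lines, parseNewick)
}

#' Write a tree (or trees) as Newick
#'
#' The writer handles missing branch lengths by omitting them (ape's writer
#' would emit literal `NaN`) and prints retained lengths with 6 significant
#' digits. Node labels can come from the tree itself or be supplied, e.g. the
#' `"f2/f4"` simulation-frequency annotations.
#'
#' @param phy A `phylo` object, or a list of them.
#' @param file Optional path; when `NULL` the Newick string(s) are returned.
#' @param digits Significant digits for branch lengths.
#' @param nodeLabels Optional character vector (length `phy$Nnode`) overriding
#'   `phy$node.label`.
#' @return Character vector of Newick strings, invisibly when writing to file.
#' @export
writeNewick <- function(phy, file = NULL, digits = 6, nodeLabels = NULL) {
  if (is.list(phy) && !inherits(phy, "phylo")) {
    out <- vapply(phy, function(p) writeNewick(p, digits = digits),
                  character(1L))
  } else {
    out <- .newickString(phy, digits = digits, nodeLabels = nodeLabels)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.newickString <- function(phy, digits = 6, nodeLabels = NULL) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  if (isTRUE(attr(phy, "singleTip")) || n == 1L)
    return(paste0(phy$tip.label[1L], ";"))
  el <- phy$edge.length
  nl <- if (!is.null(nodeLabels)) nodeLabels else phy$node.label
  kids <- .childrenList(phy)
  edgeOfChild <- integer(n + phy$Nnode)
  edgeOfChild[phy$edge[, 2L]] <- seq_len(nrow(phy$edge))
  fmtLen <- function(node) {
    if (is.null(el)) return("")
    x <- el[edgeOfChild[node]]
    if (is.na(x)) return("")
    paste0(":", format(x, digits = digits, scientific = FALSE, trim = TRUE))
  }
  root <- n + 1L
  rec <- function(node) {
    if (node <= n)
      return(paste0(phy$tip.label[node], fmtLen(node)))
    inner <- paste(vapply(kids[[node]], rec, character(1L)), collapse = ",")
    lab <- if (!is.null(nl)) nl[node - n] else ""
    if (is.na(lab)) lab <- ""
    paste0("(", inner, ")", lab, if (node != root) fmtLen(node) else "")
  }
  paste0(rec(root), ";")
}

.childrenList <- function(phy) {
  nn <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge)))
    kids[[phy$edge[i, 1L]]] <- c(kids[[phy$edge[i, 1L]]], phy$edge[i, 2L])
  kids
}

#' Rescale branch lengths by an inheritance scalar
#'
#' Multiplies every stored branch length (coalescent units) by `factor`.
#' The scalars used for organellar genomes are 2 (hermaphroditic taxa) and 4
#' (dioecious taxa): haploid, uniparentally inherited genomes have a half or a
#' quarter of the nuclear effective population size, hence a coalescence rate
#' two or four times higher. Missing lengths stay missing; topology and labels
#' are untouched.
#'
#' @param phy A `phylo` object.
#' @param factor Positive multiplier.
#' @return The rescaled `phylo`.
#' @export
rescaleBranchLengths <- function(phy, factor) {
  stopifnot(inherits(phy, "phylo"))
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0)
    stop("'factor' must be a positive number")
  if (!is.null(phy$edge.length)) {
    keep <- !is.na(phy$edge.length)
    phy$edge.length[keep] <- phy$edge.length[keep] * factor
  }
  phy
}

#' Nontrivial bipartitions of a tree, viewed unrooted
#'
#' Each internal edge of the unrooted tree splits the taxa in two; the split is
#' stored canonically as the side NOT containing the reference taxon (the
#' lexicographically smallest label), encoded as sorted indices into the
#' sorted taxon vector. Keys are therefore identical for any rooting or tip
#' ordering of the same split.
#'
#' @param phy A `phylo` object.
#' @param includeTrivial Also return the single-taxon splits.
#' @param taxa Full taxon set defining the index space; defaults to the tree's
#'   own sorted tip labels. Must be a superset-equal of the tree's tips.
#' @return Character vector of canonical split keys with attribute `taxa`.
#' @seealso [bipartitionLabels()] to decode keys.
#' @export
treeBipartitions <- function(phy, includeTrivial = FALSE, taxa = NULL) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  if (is.null(taxa)) taxa <- sort(phy$tip.label)
  idx <- match(phy$tip.label, taxa)
  if (anyNA(idx))
    stop("tree contains tips absent from 'taxa': ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "))
  if (n < 2L || phy$Nnode < 1L) {
    out <- character(0L); attr(out, "taxa") <- taxa; return(out)
  }
  masks <- .cladeMasks(phy, idx, length(taxa))
  root <- n + 1L
  nodes <- setdiff(seq.int(n + 1L, n + phy$Nnode), root)
  keys <- character(0L)
  for (v in nodes) {
    m <- masks[v - n, ]
    if (m[1L]) m <- !m
    sz <- sum(m)
    if (sz == 0L || sz == length(taxa)) next
    if (!includeTrivial && (sz < 2L || sz > length(taxa) - 2L)) next
    keys <- c(keys, paste(which(m), collapse = ","))
  }
  if (includeTrivial) {
    for (tip in seq_len(n)) {
      m <- logical(length(taxa)); m[idx[tip]] <- TRUE
      if (m[1L]) m <- !m
      keys <- c(keys, paste(which(m), collapse = ","))
    }
  }
  out <- unique(keys)
  attr(out, "taxa") <- taxa
  out
}

# logical clade-membership masks for internal nodes (rows Nnode x |taxa|),
# tip columns in the global 'taxa' index space
.cladeMasks <- function(phy, idx, nTaxa) {
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  masks <- matrix(FALSE, phy$Nnode, nTaxa)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L] - n
    ch <- po$edge[i, 2L]
    if (ch <= n) masks[p, idx[ch]] <- TRUE
    else masks[p, ] <- masks[p, ] | masks[ch - n, ]
  }
  masks
}

#' Decode canonical split keys into taxon labels
#'
#' @param keys Keys as produced by [treeBipartitions()] (its `taxa` attribute
#'   is used unless `taxa` is given).
#' @param taxa Full sorted taxon set.
#' @param side `"canonical"` for the stored side, `"smaller"` for the smaller
#'   side of the split (ties resolved to the canonical side).
#' @return List of character vectors of labels, one per key.
#' @export
bipartitionLabels <- function(keys, taxa = attr(keys, "taxa"),
                              side = c("canonical", "smaller")) {
  side <- match.arg(side)
  if (is.null(taxa)) stop("'taxa' must be supplied")
  lapply(keys, function(k) {
    i <- as.integer(strsplit(k, ",", fixed = TRUE)[[1L]])
    if (side == "smaller" && length(i) > length(taxa) - length(i))
      i <- setdiff(seq_along(taxa), i)
    taxa[i]
  })
}
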