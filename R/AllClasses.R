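#' @import methods
NULL

#' GeneTreeSet: simulated organellar gene trees
#'
#' Container for gene trees simulated under the contained coalescent within a
#' guide species tree, together with the inheritance scalar they were
#' simulated under and the master seed.
#'
#' @slot trees List of `phylo` gene trees.
#' @slot scalar Inheritance scalar applied to the guide tree before
#'   simulation.
#' @slot seed Master RNG seed (`NA` if none was set).
#' @slot tipLabels Sorted taxon set shared by all trees.
#' @export
setClass("GeneTreeSet",
  representation(trees = "list", scalar = "numeric", seed = "integer",
                 tipLabels = "character"))

setValidity("GeneTreeSet", function(object) {
  if (!length(object@trees)) return("no trees")
  taxa <- object@tipLabels
  for (i in seq_along(object@trees)) {
    t <- object@trees[[i]]
    if (!inherits(t, "phylo"))
      return(sprintf("element %d is not a 'phylo'", i))
    if (!identical(sort(t$tip.label), taxa))
      return(sprintf("tree %d tip set differs from 'tipLabels'", i))
  }
  if (length(object@scalar) != 1L || object@scalar <= 0)
    return("'scalar' must be a single positive number")
  TRUE
})

#' @describeIn GeneTreeSet Number of simulated trees.
#' @param x A `GeneTreeSet`.
#' @export
setMethod("length", "GeneTreeSet", function(x) length(x@trees))

#' Extract the list of simulated trees
#' @param x A `GeneTreeSet`.
#' @return List of `phylo` objects.
#' @export
simTrees <- function(x) {
  stopifnot(is(x, "GeneTreeSet"))
  x@trees
}

#' Inheritance scalar of a simulation
#' @param x A `GeneTreeSet`.
#' @export
scalarFactor <- function(x) {
  stopifnot(is(x, "GeneTreeSet"))
  x@scalar
}

setMethod("show", "GeneTreeSet", function(object) {
  cat(sprintf(
    "GeneTreeSet: %d contained-coalescent gene trees over %d taxa (scalar x%g, seed %s)\n",
    length(object@trees), length(object@tipLabels), object@scalar,
    ifelse(is.na(object@seed), "unset", object@seed)))
})

#' ConcordanceReport: per-branch concordance of simulations with an observed tree
#'
#' One row per nontrivial bipartition of the observed organellar tree, giving
#' the fraction of simulated gene trees containing that bipartition under each
#' inheritance scalar, whether the branch conflicts with the nuclear guide
#' tree, and the lineage-sorting verdict: a branch whose observed relationship
#' appears in at most `threshold` of the simulations under every scalar is an
#' introgression (chloroplast-capture) candidate; otherwise incomplete lineage
#' sorting remains a plausible explanation.
#'
#' @slot table `data.frame` with columns `bipartition` (smaller side of the
#'   split, comma-joined), `n_trees`, one `freq_x<scalar>` column per scalar,
#'   `conflicts_nuclear`, `classification`.
#' @slot keys Canonical split keys aligned with the rows.
#' @slot taxa Sorted shared taxon set.
#' @slot scalars Scalars evaluated.
#' @slot threshold Decision threshold on the simulated frequency.
#' @slot nTrees Simulated trees per scalar.
#' @export
setClass("ConcordanceReport",
  representation(table = "data.frame", keys = "character", taxa = "character",
                 scalars = "numeric", threshold = "numeric",
                 nTrees = "integer"))

setValidity("ConcordanceReport", function(object) {
  tab <- object@table
  if (nrow(tab) != length(object@keys))
    return("'keys' must align with table rows")
  fcols <- paste0("freq_x", .fmtScalar(object@scalars))
  if (!all(fcols %in% names(tab)))
    return("missing per-scalar frequency column(s)")
  for (fc in fcols) {
    f <- tab[[fc]]
    if (any(f < 0 | f > 1, na.rm = TRUE))
      return("frequencies must lie in [0, 1]")
  }
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    return("'threshold' must be in (0, 1)")
  TRUE
})

.fmtScalar <- function(s) sub("\\.?0+$", "", format(s, trim = TRUE))

#' Report table of a ConcordanceReport
#' @param x A `ConcordanceReport`.
#' @return The underlying `data.frame`.
#' @export
reportTable <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  x@table
}

#' Branches flagged as introgression candidates
#' @param x A `ConcordanceReport`.
#' @return Rows of the report table classified `introgression-candidate`.
#' @export
candidateBranches <- function(x) {
  stopifnot(is(x, "ConcordanceReport"))
  x@table[x@table$classification == "introgression-candidate", , drop = FALSE]
}

setMethod("show", "ConcordanceReport", function(object) {
  nc <- sum(object@table$classification == "introgression-candidate")
  cat(sprintf(
    "ConcordanceReport: %d branches, %d taxa, %d simulated trees per scalar (x%s)\n",
    nrow(object@table), length(object@taxa), object@nTrees,
    paste(.fmtScalar(object@scalars), collapse = "/x")))
  cat(sprintf("  threshold <= %g: %d introgression candidate(s), %d branch(es) conflict with the guide tree\n",
              object@threshold, nc, sum(object@table$conflicts_nuclear)))
})

#' DnaAlignment: rectangular multiple sequence alignment
#'
#' A taxa-by-columns character matrix over the DNA alphabet with IUPAC
#' ambiguity codes, gap `-` and missing `N`. Input is case-insensitive and
#' `U` is accepted as `T`; characters are stored uppercase.
#'
#' @slot seqs Character matrix, rows named by unique sequence labels.
#' @slot metadata List of provenance (generator seeds, injected-feature
#'   coordinates, kept-column indices after masking, ...).
#' @export
setClass("DnaAlignment",
  representation(seqs = "matrix", metadata = "list"))

.ALN_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")

setValidity("DnaAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("'seqs' must be a character matrix")
  if (nrow(m) < 1L) return("alignment has no sequences")
  labs <- rownames(m)
  if (is.null(labs) || any(!nzchar(labs)))
    return("sequences must have nonempty labels")
  if (anyDuplicated(labs)) return("duplicate sequence labels")
  bad <- setdiff(unique(as.vector(m)), .ALN_ALPHABET)
  if (length(bad))
    return(paste0("characters outside the alignment alphabet: ",
                  paste(bad, collapse = " ")))
  TRUE
})

#' Construct a DnaAlignment
#'
#' @param x Named character vector of equal-length sequences, or a character
#'   matrix with one row per sequence.
#' @param metadata Optional provenance list.
#' @return A [DnaAlignment-class] object.
#' @export
DnaAlignment <- function(x, metadata = list()) {
  if (is.matrix(x)) {
    m <- x
  } else {
    stopifnot(is.character(x))
    if (is.null(names(x))) stop("sequences must be named")
    w <- unique(nchar(x))
    if (length(w) > 1L)
      stop("sequences are not aligned: lengths ", paste(w, collapse = ", "))
    m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
    if (length(x) == 1L) m <- matrix(m, nrow = 1L)
    rownames(m) <- names(x)
  }
  m[] <- toupper(m)
  m[m == "U"] <- "T"
  new("DnaAlignment", seqs = m, metadata = metadata)
}

#' @describeIn DnaAlignment Dimensions (sequences, columns).
#' @param x A `DnaAlignment`.
#' @export
setMethod("dim", "DnaAlignment", function(x) dim(x@seqs))

#' Character matrix of an alignment
#' @param x A `DnaAlignment`.
#' @export
alignmentMatrix <- function(x) {
  stopifnot(is(x, "DnaAlignment"))
  x@seqs
}

#' Sequence labels of an alignment
#' @param x A `DnaAlignment`.
#' @export
sequenceLabels <- function(x) {
  stopifnot(is(x, "DnaAlignment"))
  rownames(x@seqs)
}

#' Provenance metadata of an alignment
#' @param x A `DnaAlignment`.
#' @export
alignmentMetadata <- function(x) {
  stopifnot(is(x, "DnaAlignment"))
  x@metadata
}

setMethod("show", "DnaAlignment", function(object) {
  cat(sprintf("DnaAlignment: %d sequences x %d columns\n",
              nrow(object@seqs), ncol(object@seqs)))
})
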