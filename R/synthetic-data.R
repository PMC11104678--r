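#' Generate a synthetic guide species tree
#'
#' Emulates the kind of guide tree a summary coalescent method (e.g. ASTRAL)
#' produces: a random birth-process topology with internal branch lengths in
#' coalescent units and terminal branch lengths absent. Internal lengths are
#' drawn i.i.d. from an exponential distribution (controllable ILS level via
#' its mean) or fixed to a constant.
#'
#' @param nTips Number of tips (>= 4); labels follow the `"T0001"` scheme.
#' @param seed RNG seed or `NULL`.
#' @param lengthDistribution `"exponential"` or `"fixed"` internal lengths.
#' @param meanLength Mean of the exponential, in CU.
#' @param fixedLength Constant internal length, in CU (used when
#'   `lengthDistribution = "fixed"`).
#' @return A rooted `phylo`; terminal branch lengths are `NA` (absent).
#' @export
simulateGuideTree <- function(nTips, seed = NULL,
                              lengthDistribution = c("exponential", "fixed"),
                              meanLength = 1.0, fixedLength = 1.0) {
  lengthDistribution <- match.arg(lengthDistribution)
  if (!is.numeric(nTips) || nTips < 4L)
    stop("'nTips' must be >= 4")
  nTips <- as.integer(nTips)
  if (!is.null(seed)) set.seed(as.integer(seed))
  phy <- ape::rtree(nTips, br = NULL)
  phy$tip.label <- sprintf("T%04d", seq_len(nTips))
  nInt <- sum(phy$edge[, 2L] > nTips)
  intLen <- switch(lengthDistribution,
    exponential = stats::rexp(nInt, rate = 1 / meanLength),
    fixed = rep(fixedLength, nInt))
  el <- rep(NA_real_, nrow(phy$edge))
  el[phy$edge[, 2L] > nTips] <- intLen
  phy$edge.length <- el
  phy
}

#' Apply a chloroplast-capture move
#'
#' Models plastome capture following hybridisation and backcrossing as a
#' topology-level subtree-prune-and-regraft: the recipient clade is pruned
#' and reattached as sister to the donor clade; all other relationships are
#' unchanged. The returned tree is topology-only (no branch lengths), since
#' the downstream decision rule consumes only the observed topology.
#'
#' @param phy A `phylo` (>= 4 tips).
#' @param donor Tip labels of the donor clade (must be a clade).
#' @param recipient Tip labels of the recipient clade (a clade, disjoint from
#'   and not nested with the donor).
#' @return A rooted `phylo` without branch lengths.
#' @export
applyChloroplastCapture <- function(phy, donor, recipient) {
  stopifnot(inherits(phy, "phylo"))
  donor <- as.character(donor); recipient <- as.character(recipient)
  if (!length(donor) || !length(recipient))
    stop("'donor' and 'recipient' must be nonempty")
  if (length(intersect(donor, recipient)))
    stop("donor and recipient clades must be disjoint")
  missingTips <- setdiff(c(donor, recipient), phy$tip.label)
  if (length(missingTips))
    stop("unknown tip(s): ", paste(missingTips, collapse = ", "))
  .assertClade(phy, donor, "donor")
  .assertClade(phy, recipient, "recipient")
  if (length(recipient) >= length(phy$tip.label) - 1L)
    stop("recipient clade leaves no backbone to regraft onto")
  subText <- .subtreeText(phy, recipient)
  backbone <- ape::drop.tip(phy, recipient, collapse.singles = TRUE)
  backbone$edge.length <- NULL
  backbone$node.label <- NULL
  donorNode <- .cladeNode(backbone, donor)
  parseNewick(.newickWithGraft(backbone, donorNode, subText))
}

.cladeNode <- function(phy, tips) {
  if (length(tips) == 1L) return(match(tips, phy$tip.label))
  ape::getMRCA(phy, tips)
}

.assertClade <- function(phy, tips, what) {
  if (length(tips) == 1L) return(invisible(TRUE))
  node <- ape::getMRCA(phy, tips)
  desc <- phy$tip.label[.tipsBelow(phy, node)]
  if (!setequal(desc, tips))
    stop("'", what, "' is not a clade: its MRCA also contains ",
         paste(setdiff(desc, tips), collapse = ", "))
  invisible(TRUE)
}

.tipsBelow <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  kids <- .childrenList(phy)
  out <- integer(0L)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (ch in kids[[v]]) {
      if (ch <= n) out <- c(out, ch) else stack <- c(stack, ch)
    }
  }
  out
}

# Topology-only Newick of the subtree rooted at the clade spanning 'tips'
.subtreeText <- function(phy, tips) {
  node <- .cladeNode(phy, tips)
  n <- length(phy$tip.label)
  kids <- .childrenList(phy)
  rec <- function(v) {
    if (v <= n) return(phy$tip.label[v])
    paste0("(", paste(vapply(kids[[v]], rec, character(1L)), collapse = ","),
           ")")
  }
  rec(node)
}

# Topology-only Newick of 'phy' with 'graftText' inserted as sister to the
# clade at 'donorNode'
.newickWithGraft <- function(phy, donorNode, graftText) {
  n <- length(phy$tip.label)
  kids <- .childrenList(phy)
  root <- n + 1L
  rec <- function(v) {
    s <- if (v <= n) phy$tip.label[v]
         else paste0("(", paste(vapply(kids[[v]], rec, character(1L)),
                                collapse = ","), ")")
    if (v == donorNode) s <- paste0("(", s, ",", graftText, ")")
    s
  }
  paste0(rec(root), ";")
}

#' Generate an observed organellar tree under a scenario
#'
#' Under `"pure_ils"` the observed tree is one contained-coalescent draw from
#' the guide tree (the truth is lineage sorting); under `"capture"` it is the
#' guide-tree topology with a chloroplast-capture move applied (the truth is
#' introgression).
#'
#' @param guide Guide species tree (`phylo`) with internal CU lengths.
#' @param scenario `"pure_ils"` or `"capture"`.
#' @param seed RNG seed for the pure-ILS draw.
#' @param scalar Inheritance scalar for the pure-ILS draw (default 2, the
#'   hermaphroditic plastome).
#' @param donor,recipient Clade tip labels for the capture move.
#' @param missingLengthPolicy,missingLengthValue Passed to the simulator.
#' @return A `phylo` observed tree.
#' @export
makeObservedTree <- function(guide, scenario = c("pure_ils", "capture"),
                             seed = NULL, scalar = 2,
                             donor = NULL, recipient = NULL,
                             missingLengthPolicy = "error",
                             missingLengthValue = 0) {
  scenario <- match.arg(scenario)
  if (scenario == "pure_ils") {
    sims <- simulateGeneTrees(guide, nTrees = 1L, scalar = scalar,
                              seed = seed,
                              missingLengthPolicy = missingLengthPolicy,
                              missingLengthValue = missingLengthValue)
    return(simTrees(sims)[[1L]])
  }
  if (is.null(donor) || is.null(recipient))
    stop("capture scenario needs 'donor' and 'recipient'")
  applyChloroplastCapture(guide, donor, recipient)
}

#' Evolve a toy alignment under JC69 with injected gap/N blocks
#'
#' Sequences evolve under the Jukes-Cantor model on a tree with
#' substitution-scale branch lengths (CU trees must be rescaled by a stated
#' factor first); `rate` multiplies all branch lengths, so `rate = 0` returns
#' identical copies of the root sequence. Gap or N blocks are then stamped at
#' the requested coordinates, which are recorded in the metadata so masking
#' expectations in downstream tests are exact.
#'
#' @param phy A `phylo` with branch lengths.
#' @param nSites Number of alignment columns (> 0).
#' @param rate Multiplier on branch lengths.
#' @param gapBlocks List of blocks, each a list with `rows` (tip labels, or
#'   `NULL` for all), `cols` (column indices) and `char` (`"-"` or `"N"`).
#' @param seed RNG seed or `NULL`.
#' @return A [DnaAlignment-class]; metadata records `seed`, `rate` and
#'   `gapBlocks`.
#' @export
evolveJC69WithGaps <- function(phy, nSites, rate = 1, gapBlocks = list(),
                               seed = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (!is.numeric(nSites) || nSites <= 0) stop("'nSites' must be > 0")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("tree must have substitution-scale branch lengths on every edge")
  if (rate < 0) stop("'rate' must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- phy
  tr$edge.length <- tr$edge.length * rate
  sim <- phangorn::simSeq(tr, l = as.integer(nSites), type = "DNA")
  cm <- as.character(sim)
  m <- toupper(cm)
  dim(m) <- dim(cm)
  dimnames(m) <- dimnames(cm)
  for (b in gapBlocks) {
    rows <- if (is.null(b$rows)) rownames(m) else as.character(b$rows)
    ch <- if (is.null(b$char)) "-" else b$char
    stopifnot(ch %in% c("-", "N"), all(rows %in% rownames(m)),
              all(b$cols >= 1L & b$cols <= ncol(m)))
    m[rows, b$cols] <- ch
  }
  DnaAlignment(m, metadata = list(
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    rate = rate, gapBlocks = gapBlocks))
}
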