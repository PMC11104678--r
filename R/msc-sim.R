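#' Simulate gene trees under the contained (censored) coalescent
#'
#' Draws organellar gene trees under the neutral multispecies coalescent
#' constrained to the branches of a guide species tree whose internal branch
#' lengths are in coalescent units (CU). Before simulation the guide tree's
#' branch lengths are multiplied by the inheritance `scalar` (2 for
#' hermaphroditic, 4 for dioecious taxa), which is exactly equivalent to the
#' organellar genome's proportionally higher coalescence rate.
#'
#' One gene lineage is sampled per species tip. Looking backward in time,
#' within each species-tree branch of length `L` carrying `k` lineages,
#' successive waiting times are drawn from Exponential(rate = k(k-1)/2) CU; at
#' each event that falls within `L` a uniformly random pair of lineages merges
#' and the survivors are passed to the parent branch. The branch above the
#' root is infinite, so all remaining lineages coalesce there. A polytomy of
#' degree d passes all d children's surviving lineages jointly into the parent
#' branch (the coalescent semantics of an unresolved radiation).
#'
#' Terminal branches default to 0 CU: with one sampled allele per species no
#' coalescence can occur there, so the value is immaterial (guide trees from
#' summary methods such as ASTRAL lack terminal CU lengths). Missing internal
#' lengths are an error by default; set `missingLengthPolicy = "substitute"`
#' to replace them with `missingLengthValue` CU (0, the ILS-maximising
#' conservative choice, by default).
#'
#' Each tree is drawn from its own seed derived from the master `seed`, so a
#' run is reproducible and the i-th tree does not depend on how many trees are
#' requested before it.
#'
#' @param guide Guide species tree (`phylo`), rooted, internal branch lengths
#'   in CU.
#' @param nTrees Number of gene trees to simulate.
#' @param scalar Positive inheritance scalar.
#' @param seed Master RNG seed (integer) or `NULL`.
#' @param missingLengthPolicy `"error"` or `"substitute"` for missing internal
#'   branch lengths.
#' @param missingLengthValue CU value substituted under
#'   `missingLengthPolicy = "substitute"`.
#' @return A [GeneTreeSet-class].
#' @examples
#' guide <- parseNewick("((A:0,B:0):1.0,C:0);")
#' sims <- simulateGeneTrees(guide, nTrees = 200, scalar = 2, seed = 1)
#' sims
#' @export
simulateGeneTrees <- function(guide, nTrees = 1000, scalar = 2, seed = NULL,
                              missingLengthPolicy = c("error", "substitute"),
                              missingLengthValue = 0) {
  stopifnot(inherits(guide, "phylo"))
  missingLengthPolicy <- match.arg(missingLengthPolicy)
  if (!is.numeric(nTrees) || nTrees < 1)
    stop("'nTrees' must be >= 1")
  nTrees <- as.integer(nTrees)
  prep <- .prepareGuide(guide, scalar, missingLengthPolicy,
                        missingLengthValue)
  if (!is.null(seed)) set.seed(as.integer(seed))
  treeSeeds <- sample.int(.Machine$integer.max - 1L, nTrees)
  trees <- vector("list", nTrees)
  for (i in seq_len(nTrees)) {
    set.seed(treeSeeds[i])
    trees[[i]] <- .simulateContained(prep)
  }
  new("GeneTreeSet", trees = trees, scalar = as.numeric(scalar),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      tipLabels = sort(guide$tip.label))
}

#' Simulate a single contained gene tree
#'
#' One draw of the contained coalescent (see [simulateGeneTrees()] for the
#' model). Uses the current RNG state.
#'
#' @inheritParams simulateGeneTrees
#' @return A `phylo` gene tree over the guide tree's tips, with branch lengths
#'   in rescaled CU (informational; the topology is the contract).
#' @export
simulateContainedTree <- function(guide, scalar = 1,
                                  missingLengthPolicy = c("error", "substitute"),
                                  missingLengthValue = 0) {
  missingLengthPolicy <- match.arg(missingLengthPolicy)
  prep <- .prepareGuide(guide, scalar, missingLengthPolicy,
                        missingLengthValue)
  .simulateContained(prep)
}

# Resolve branch-length policies, apply the scalar, and precompute the
# postorder traversal structures the simulator needs.
.prepareGuide <- function(phy, scalar, missingLengthPolicy = "error",
                          missingLengthValue = 0) {
  if (!is.numeric(scalar) || length(scalar) != 1L || is.na(scalar) ||
      scalar <= 0)
    stop("'scalar' must be a single positive number")
  if (missingLengthValue < 0)
    stop("'missingLengthValue' must be >= 0")
  n <- length(phy$tip.label)
  if (n < 2L) stop("guide tree must have at least 2 tips")
  if (!ape::is.rooted(phy)) stop("guide tree must be rooted")
  nn <- n + phy$Nnode
  root <- n + 1L
  parent <- integer(nn)
  len <- rep(NA_real_, nn)         # length of the edge above each node
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; ch <- phy$edge[i, 2L]
    parent[ch] <- p
    len[ch] <- if (is.null(phy$edge.length)) NA_real_ else phy$edge.length[i]
  }
  len[is.nan(len)] <- NA_real_
  # terminal policy: default 0 CU
  termNA <- which(seq_len(nn) <= n & is.na(len))
  len[termNA] <- 0
  intNA <- which(seq_len(nn) > n & seq_len(nn) != root & is.na(len))
  if (length(intNA)) {
    if (missingLengthPolicy == "error")
      stop("missing coalescent-unit length on internal edge above node(s) ",
           paste(intNA, collapse = ", "),
           "; use missingLengthPolicy = \"substitute\" to assign a value")
    len[intNA] <- missingLengthValue
  }
  len <- len * scalar
  len[root] <- Inf
  # depths (distance from the root) give gene-node times on a shared axis
  po <- ape::reorder.phylo(phy, "postorder")
  preOrderEdges <- nrow(po$edge):1
  depth <- numeric(nn)
  for (i in preOrderEdges) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    depth[ch] <- depth[p] + len[ch]
  }
  kids <- vector("list", nn)
  for (i in seq_len(nrow(po$edge)))
    kids[[po$edge[i, 1L]]] <- c(kids[[po$edge[i, 1L]]], po$edge[i, 2L])
  # internal nodes in postorder (children always precede parents)
  postInternal <- unique(po$edge[, 1L])
  list(n = n, root = root, len = len, depth = depth, kids = kids,
       postInternal = postInternal, tipLabels = phy$tip.label)
}

.simulateContained <- function(prep) {
  n <- prep$n
  nMerge <- n - 1L
  mergeL <- integer(nMerge); mergeR <- integer(nMerge)
  mergeT <- numeric(nMerge)
  nm <- 0L
  active <- vector("list", length(prep$len))  # lineages leaving each node
  for (tip in seq_len(n)) active[[tip]] <- tip
  for (v in prep$postInternal) {
    A <- unlist(active[prep$kids[[v]]], use.names = FALSE)
    k <- length(A)
    L <- prep$len[v]
    t <- 0
    while (k >= 2L) {
      w <- stats::rexp(1L, rate = k * (k - 1L) / 2)
      if (t + w > L) break
      t <- t + w
      pair <- sample.int(k, 2L)
      nm <- nm + 1L
      mergeL[nm] <- A[pair[1L]]
      mergeR[nm] <- A[pair[2L]]
      mergeT[nm] <- prep$depth[v] - t
      A <- c(A[-pair], n + nm)
      k <- k - 1L
    }
    active[[v]] <- A
  }
  .mergesToPhylo(n, mergeL, mergeR, mergeT, prep$tipLabels, prep$depth)
}

# Assemble a cladewise phylo from the merge history. Temporary internal ids
# are n+1..2n-1 in creation order; the final merge is the gene-tree root.
.mergesToPhylo <- function(n, mergeL, mergeR, mergeT, tipLabels, depth) {
  nNode <- n - 1L
  nn <- n + nNode
  chA <- c(integer(n), mergeL)
  chB <- c(integer(n), mergeR)
  tm <- c(depth[seq_len(n)], mergeT)
  newId <- integer(nn)
  edge <- matrix(0L, 2L * n - 2L, 2L)
  edgeLen <- numeric(2L * n - 2L)
  nextEdge <- 1L
  rootTmp <- nn
  newId[rootTmp] <- n + 1L
  nextInternal <- n + 2L
  # depth-first edge order (cladewise): stack of (parent, child) pairs
  stackP <- rootTmp
  stackC <- chB[rootTmp]
  stackP <- c(stackP, rootTmp)
  stackC <- c(stackC, chA[rootTmp])
  while (length(stackC)) {
    k <- length(stackC)
    p <- stackP[k]; ch <- stackC[k]
    stackP <- stackP[-k]; stackC <- stackC[-k]
    if (ch > n) {
      newId[ch] <- nextInternal
      nextInternal <- nextInternal + 1L
    } else newId[ch] <- ch
    edge[nextEdge, ] <- c(newId[p], newId[ch])
    edgeLen[nextEdge] <- tm[ch] - tm[p]
    nextEdge <- nextEdge + 1L
    if (ch > n) {
      stackP <- c(stackP, ch, ch)
      stackC <- c(stackC, chB[ch], chA[ch])
    }
  }
  structure(list(edge = edge, edge.length = edgeLen,
                 tip.label = tipLabels, Nnode = nNode),
            class = "phylo", order = "cladewise")
}
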