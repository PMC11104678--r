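# Independent oracles used across the suite. These deliberately share no code
# with the package internals: the MSC oracle works on a nested-list tree and
# draws one exponential clock per lineage pair (taking the minimum), rather
# than a single pooled exponential plus a uniform pair choice.

# phylo -> nested list; each node: list(children=..., len=edge length above)
nestedTree <- function(phy, terminalLength = 0) {
  n <- length(phy$tip.label)
  kids <- vector("list", n + phy$Nnode)
  lens <- rep(NA_real_, n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; ch <- phy$edge[i, 2]
    kids[[p]] <- c(kids[[p]], ch)
    lens[ch] <- if (is.null(phy$edge.length)) NA else phy$edge.length[i]
  }
  build <- function(v) {
    len <- lens[v]
    if (v <= n) {
      if (is.na(len)) len <- terminalLength
      return(list(label = phy$tip.label[v], len = len))
    }
    if (is.na(len)) len <- 0
    list(children = lapply(kids[[v]], build), len = len)
  }
  node <- build(n + 1)
  node$len <- Inf
  node
}

# One gene-tree draw under the contained coalescent; lineages are clades
# (character vectors of labels). Returns the rooted topology as a canonical
# string: sorted internal-clade strings joined by "|".
oracleContainedDraw <- function(node) {
  clades <- character(0)
  coalesce <- function(nd) {
    lin <- if (!is.null(nd$label)) list(nd$label)
           else do.call(c, lapply(nd$children, coalesce))
    elapsed <- 0
    while (length(lin) >= 2) {
      k <- length(lin)
      pairs <- utils::combn(k, 2)
      waits <- stats::rexp(ncol(pairs), rate = 1)
      j <- which.min(waits)
      if (elapsed + waits[j] > nd$len) break
      elapsed <- elapsed + waits[j]
      merged <- sort(c(lin[[pairs[1, j]]], lin[[pairs[2, j]]]))
      clades[[length(clades) + 1]] <<- paste(merged, collapse = ",")
      lin <- c(lin[-pairs[, j]], list(merged))
    }
    lin
  }
  coalesce(node)
  paste(sort(clades), collapse = "|")
}

# canonical rooted-topology key of a phylo, comparable with the oracle's
rootedTopologyKey <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  clades <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = ","),
                   character(1))
  paste(sort(clades), collapse = "|")
}

# the two tips forming the cherry of a rooted triplet gene tree
cherryPair <- function(phy) {
  n <- length(phy$tip.label)
  for (v in (n + 1):(n + phy$Nnode)) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    if (all(ch <= n) && length(ch) == 2)
      return(sort(phy$tip.label[ch]))
  }
  stop("no cherry found")
}

# brute-force parsimony-informative-site counter (per-column tabulation)
bruteForcePIS <- function(m) {
  sum(apply(m, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2) >= 2
  }))
}

# random test alignment over the full input alphabet
randomAlignment <- function(nSeq, nCol) {
  alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N", "-")
  probs <- c(rep(5, 4), rep(0.3, 10), 1, 2)
  m <- matrix(sample(alphabet, nSeq * nCol, replace = TRUE,
                     prob = probs / sum(probs)), nSeq, nCol)
  rownames(m) <- sprintf("s%02d", seq_len(nSeq))
  DnaAlignment(m)
}

# chi-square comparison of two topology-count spectra, pooling rare classes
spectraChisqP <- function(c1, c2, minTotal = 10) {
  keys <- union(names(c1), names(c2))
  x1 <- ifelse(keys %in% names(c1), c1[keys], 0)
  x2 <- ifelse(keys %in% names(c2), c2[keys], 0)
  tot <- x1 + x2
  pool <- tot < minTotal
  if (any(pool)) {
    x1 <- c(x1[!pool], sum(x1[pool]))
    x2 <- c(x2[!pool], sum(x2[pool]))
  }
  keepCol <- (x1 + x2) > 0
  x1 <- x1[keepCol]; x2 <- x2[keepCol]
  if (length(x1) < 2) return(1)
  suppressWarnings(stats::chisq.test(rbind(x1, x2))$p.value)
}
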