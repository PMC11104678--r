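#' Per-branch concordance frequencies of simulated trees
#'
#' For each nontrivial bipartition of the observed organellar tree (viewed
#' unrooted), computes the fraction of simulated gene trees whose own
#' bipartition set contains it. Rooting of either side is ignored; the
#' fraction is over exactly the number of simulated trees.
#'
#' @param observed Observed organellar tree (`phylo`).
#' @param sims A [GeneTreeSet-class] or a list of `phylo` trees over the same
#'   taxon set.
#' @return Named numeric vector of fractions in `[0, 1]`; names are canonical
#'   split keys (attribute `taxa` gives the taxon index space).
#' @export
cladeFrequencies <- function(observed, sims) {
  stopifnot(inherits(observed, "phylo"))
  trees <- if (is(sims, "GeneTreeSet")) sims@trees else sims
  if (!length(trees)) stop("no simulated trees supplied")
  taxa <- sort(observed$tip.label)
  for (i in seq_along(trees)) {
    st <- sort(trees[[i]]$tip.label)
    if (!identical(st, taxa)) {
      d <- c(setdiff(st, taxa), setdiff(taxa, st))
      stop("tip-set mismatch between observed and simulated tree ", i,
           "; differing taxa: ", paste(d, collapse = ", "))
    }
  }
  obsKeys <- treeBipartitions(observed, taxa = taxa)
  counts <- integer(length(obsKeys))
  for (tr in trees) {
    simKeys <- treeBipartitions(tr, taxa = taxa)
    counts <- counts + (obsKeys %in% simKeys)
  }
  out <- counts / length(trees)
  names(out) <- obsKeys
  attr(out, "taxa") <- taxa
  out
}

#' Classify one branch under the ILS-plausibility rule
#'
#' A branch is an introgression candidate under a scalar when its observed
#' relationship occurred in at most `threshold` (default 1%) of the gene trees
#' simulated under pure lineage sorting; the comparison is an exact `<=` on
#' the reported fraction, so a branch sitting exactly at the threshold is a
#' candidate. The combined verdict requires the frequency to be at or below
#' the threshold under every evaluated scalar.
#'
#' @param freqs Named numeric vector of simulated frequencies, one per scalar
#'   (e.g. `c("2" = 0.074, "4" = 0.026)`).
#' @param threshold Decision threshold in (0, 1).
#' @return List with `perScalar` (character vector of verdicts by scalar) and
#'   `combined` (single verdict), values `"ILS-plausible"` or
#'   `"introgression-candidate"`.
#' @examples
#' classifyBranch(c("2" = 0.29, "4" = 0.29))$combined      # ILS-plausible
#' classifyBranch(c("2" = 0.009, "4" = 0.001))$combined    # candidate
#' @export
classifyBranch <- function(freqs, threshold = 0.01) {
  if (!length(freqs)) stop("at least one scalar frequency is required")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")
  flag <- freqs <= threshold
  per <- ifelse(flag, "introgression-candidate", "ILS-plausible")
  names(per) <- names(freqs)
  list(perScalar = per,
       combined = if (all(flag)) "introgression-candidate" else "ILS-plausible")
}

#' Build a per-branch concordance report
#'
#' Assembles simulated frequencies under each scalar into one row per
#' nontrivial bipartition of the observed tree, flags branches conflicting
#' with the nuclear guide tree, and applies the decision rule of
#' [classifyBranch()].
#'
#' @param observed Observed organellar tree (`phylo`).
#' @param guide Nuclear guide tree (`phylo`) over the same taxa, used only to
#'   flag conflicting branches.
#' @param simsByScalar List of [GeneTreeSet-class] objects (typically scalars
#'   2 and 4).
#' @param threshold Decision threshold.
#' @return A [ConcordanceReport-class].
#' @export
concordanceReport <- function(observed, guide, simsByScalar,
                              threshold = 0.01) {
  stopifnot(inherits(observed, "phylo"), inherits(guide, "phylo"))
  if (is(simsByScalar, "GeneTreeSet")) simsByScalar <- list(simsByScalar)
  scalars <- vapply(simsByScalar, scalarFactor, numeric(1L))
  if (anyDuplicated(scalars)) stop("duplicate scalars in 'simsByScalar'")
  o <- order(scalars)
  simsByScalar <- simsByScalar[o]
  scalars <- scalars[o]
  taxa <- sort(observed$tip.label)
  if (!identical(sort(guide$tip.label), taxa))
    stop("guide and observed trees have different taxon sets")
  freqs <- lapply(simsByScalar, function(s) cladeFrequencies(observed, s))
  keys <- names(freqs[[1L]])
  guideKeys <- treeBipartitions(guide, taxa = taxa)
  smaller <- vapply(bipartitionLabels(keys, taxa = taxa, side = "smaller"),
                    paste, character(1L), collapse = ",")
  nT <- length(simsByScalar[[1L]])
  tab <- data.frame(bipartition = smaller, n_trees = nT,
                    stringsAsFactors = FALSE)
  for (j in seq_along(scalars))
    tab[[paste0("freq_x", .fmtScalar(scalars[j]))]] <-
      unname(freqs[[j]][keys])
  tab$conflicts_nuclear <- !(keys %in% guideKeys)
  fmat <- do.call(cbind, lapply(freqs, function(f) unname(f[keys])))
  tab$classification <- apply(fmat, 1L, function(f)
    classifyBranch(stats::setNames(f, scalars), threshold)$combined)
  new("ConcordanceReport", table = tab, keys = as.character(keys),
      taxa = taxa, scalars = as.numeric(scalars),
      threshold = threshold, nTrees = as.integer(nT))
}

#' Annotate the observed tree with simulated concordance frequencies
#'
#' Labels each internal node of the observed tree with the per-scalar
#' simulated frequencies in percent with one decimal, joined by `/` in
#' ascending-scalar order — e.g. `"7.4/2.6"` for 7.4% under x2 and 2.6% under
#' x4. Nodes whose split is trivial (or the root) get an empty label.
#'
#' @param observed Observed tree (`phylo`), the one the report was built on.
#' @param report A [ConcordanceReport-class].
#' @return `observed` with `node.label` set to the annotations.
#' @export
annotateTree <- function(observed, report) {
  stopifnot(inherits(observed, "phylo"), is(report, "ConcordanceReport"))
  taxa <- report@taxa
  n <- length(observed$tip.label)
  idx <- match(observed$tip.label, taxa)
  if (anyNA(idx)) stop("observed tree taxa differ from the report's")
  masks <- .cladeMasks(observed, idx, length(taxa))
  fcols <- paste0("freq_x", .fmtScalar(report@scalars))
  labByKey <- apply(report@table[, fcols, drop = FALSE], 1L, function(f)
    paste(formatC(100 * f, format = "f", digits = 1), collapse = "/"))
  names(labByKey) <- report@keys
  labs <- character(observed$Nnode)
  seen <- character(0L)
  for (v in seq_len(observed$Nnode)) {
    m <- masks[v, ]
    if (m[1L]) m <- !m
    key <- paste(which(m), collapse = ",")
    # a rooted tree shows the split next to the root twice; label it once
    if (key %in% seen) next
    if (!is.na(labByKey[key])) {
      labs[v] <- labByKey[[key]]
      seen <- c(seen, key)
    }
  }
  observed$node.label <- labs
  observed
}

#' Write a concordance report as a tab-separated table
#'
#' Columns: `bipartition` (smaller side of the split, comma-joined labels),
#' `n_trees`, one `freq_x<scalar>` column per scalar, `conflicts_nuclear`,
#' `classification`.
#'
#' @param report A [ConcordanceReport-class].
#' @param file Output path.
#' @export
writeReportTable <- function(report, file) {
  stopifnot(is(report, "ConcordanceReport"))
  utils::write.table(report@table, file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
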