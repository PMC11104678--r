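#' Read a FASTA multiple sequence alignment
#'
#' Labels are truncated at the first whitespace; sequences are validated as a
#' rectangular alignment over the DNA + IUPAC + gap/N alphabet (case-folded,
#' `U` treated as `T`).
#'
#' @param file Path to a FASTA file.
#' @return A [DnaAlignment-class].
#' @export
readFastaAlignment <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  if (!length(ss)) stop("no sequences in ", file)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  DnaAlignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln A [DnaAlignment-class].
#' @param file Output path.
#' @param width Line-wrapping width.
#' @export
writeFastaAlignment <- function(aln, file, width = 80) {
  stopifnot(is(aln, "DnaAlignment"))
  m <- alignmentMatrix(aln)
  ss <- Biostrings::BStringSet(apply(m, 1L, paste, collapse = ""))
  names(ss) <- rownames(m)
  Biostrings::writeXStringSet(ss, filepath = file, width = width)
  invisible(file)
}

#' Mask columns above a gap-fraction threshold
#'
#' Reproduces the threshold-masking trimmer: optionally converts every `N` to
#' `-` first, then removes each column whose gap fraction is strictly greater
#' than `maxGapFraction`. With the default 0.99 this deletes columns where
#' more than 99% of the samples have a gap — i.e. columns containing only
#' missing data or autapomorphic insertions (present in at most 1% of rows).
#' A column with a gap fraction exactly equal to the threshold is kept.
#'
#' @param aln A [DnaAlignment-class].
#' @param maxGapFraction Columns with gap fraction strictly above this are
#'   removed; in `[0, 1]`.
#' @param nAsGap Convert `N` to `-` before computing gap fractions (the
#'   conversion is kept in the output).
#' @return A [DnaAlignment-class] of the kept columns; its metadata records
#'   `keptColumns` and `removedColumns` (indices into the input).
#' @export
maskGappyColumns <- function(aln, maxGapFraction = 0.99, nAsGap = TRUE) {
  stopifnot(is(aln, "DnaAlignment"))
  if (!is.numeric(maxGapFraction) || maxGapFraction < 0 || maxGapFraction > 1)
    stop("'maxGapFraction' must be in [0, 1]")
  m <- alignmentMatrix(aln)
  if (ncol(m) == 0L) stop("empty alignment")
  if (nAsGap) m[m == "N"] <- "-"
  gapFrac <- colMeans(m == "-")
  keep <- which(gapFrac <= maxGapFraction)
  meta <- alignmentMetadata(aln)
  meta$keptColumns <- keep
  meta$removedColumns <- setdiff(seq_len(ncol(m)), keep)
  new("DnaAlignment", seqs = m[, keep, drop = FALSE], metadata = meta)
}

#' Kept-column indices recorded by masking
#' @param aln A [DnaAlignment-class] returned by [maskGappyColumns()].
#' @return Integer vector of input-column indices that were kept.
#' @export
keptColumns <- function(aln) {
  stopifnot(is(aln, "DnaAlignment"))
  aln@metadata$keptColumns
}

#' RY-recode an alignment
#'
#' Collapses the four nucleotides into purines (A, G -> R) and pyrimidines
#' (C, T -> Y), the two-state coding used to damp substitution saturation and
#' compositional bias. Gaps are unchanged and existing R/Y are fixed points.
#' All other ambiguity codes, and N, become `N`: a code spanning both
#' categories (e.g. W = A/T) carries no purine/pyrimidine information, and
#' collapsing the rest to missing is the information-conservative choice.
#' The output alphabet is a subset of `{R, Y, N, -}`.
#'
#' @param aln A [DnaAlignment-class].
#' @return The recoded [DnaAlignment-class].
#' @export
ryRecode <- function(aln) {
  stopifnot(is(aln, "DnaAlignment"))
  m <- alignmentMatrix(aln)
  map <- c(A = "R", G = "R", C = "Y", T = "Y", R = "R", Y = "Y", "-" = "-")
  out <- map[m]
  out[is.na(out)] <- "N"
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  new("DnaAlignment", seqs = out, metadata = alignmentMetadata(aln))
}

#' Alignment summary statistics
#'
#' Degapped length counts characters that are neither `-` nor `N`. A column
#' is parsimony-informative when at least two distinct unambiguous bases
#' (A, C, G, T) each occur in at least two sequences; gaps, N and ambiguity
#' codes are not states.
#'
#' @param aln A [DnaAlignment-class].
#' @return List with `length`, `nSequences`, `degappedLengths` (named
#'   per-sequence vector), `meanDegapped`, `minDegapped`, `maxDegapped`,
#'   `parsimonyInformativeSites`.
#' @export
alignmentStats <- function(aln) {
  stopifnot(is(aln, "DnaAlignment"))
  m <- alignmentMatrix(aln)
  degapped <- rowSums(m != "-" & m != "N")
  list(length = ncol(m),
       nSequences = nrow(m),
       degappedLengths = degapped,
       meanDegapped = mean(degapped),
       minDegapped = min(degapped),
       maxDegapped = max(degapped),
       parsimonyInformativeSites = countParsimonyInformative(aln))
}

#' Count parsimony-informative sites
#'
#' @inheritParams alignmentStats
#' @return Integer count of parsimony-informative columns.
#' @export
countParsimonyInformative <- function(aln) {
  stopifnot(is(aln, "DnaAlignment"))
  m <- alignmentMatrix(aln)
  if (ncol(m) == 0L) return(0L)
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L)
  sum(rowSums(counts >= 2L) >= 2L)
}

#' One-row statistics table for one or more alignments
#'
#' @param alns A [DnaAlignment-class] or named list of them.
#' @param file Optional path; when given the table is written as TSV.
#' @return `data.frame` with one row per alignment: `alignment`, `n_sequences`,
#'   `alignment_length`, `n_pis`, `mean_degapped`, `min_degapped`,
#'   `max_degapped`.
#' @export
alignmentStatsTable <- function(alns, file = NULL) {
  if (is(alns, "DnaAlignment")) alns <- list(alignment = alns)
  if (is.null(names(alns))) names(alns) <- paste0("aln", seq_along(alns))
  rows <- lapply(names(alns), function(nm) {
    s <- alignmentStats(alns[[nm]])
    data.frame(alignment = nm, n_sequences = s$nSequences,
               alignment_length = s$length, n_pis = s$parsimonyInformativeSites,
               mean_degapped = s$meanDegapped, min_degapped = s$minDegapped,
               max_degapped = s$maxDegapped, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.table(tab, file = file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
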