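#' Run the full ILS-vs-introgression test
#'
#' End-to-end analysis: reads the nuclear guide tree (internal branch lengths
#' in coalescent units) and the observed organellar tree, simulates `nTrees`
#' contained-coalescent gene trees under each inheritance scalar, summarises
#' per-branch concordance frequencies on the observed tree, applies the
#' `<= threshold` decision rule, and writes an annotated Newick, a TSV report
#' and a reproducibility manifest to `outDir`.
#'
#' @param guide Guide tree: a `phylo` or a path to a Newick file.
#' @param observed Observed organellar tree: a `phylo` or a Newick path.
#' @param nTrees Simulated trees per scalar (default 1000).
#' @param scalars Inheritance scalars (default `c(2, 4)`).
#' @param threshold Decision threshold on the simulated frequency
#'   (default 0.01).
#' @param seed Master seed; per-scalar and per-tree seeds are derived from it.
#' @param outDir Output directory (created if needed), or `NULL` to skip all
#'   file output.
#' @param missingLengthPolicy,missingLengthValue Policy for missing internal
#'   CU lengths (see [simulateGeneTrees()]).
#' @param keepSims Also write each scalar's simulated trees as multi-tree
#'   Newick files.
#' @return A [ConcordanceReport-class], invisibly when writing files.
#' @examples
#' guide <- simulateGuideTree(10, seed = 7, lengthDistribution = "fixed",
#'                            fixedLength = 3)
#' obs <- makeObservedTree(guide, "pure_ils", seed = 8,
#'                         missingLengthPolicy = "substitute")
#' rep <- runIlsTest(guide, obs, nTrees = 100, seed = 9, outDir = NULL,
#'                   missingLengthPolicy = "substitute")
#' rep
#' @export
runIlsTest <- function(guide, observed, nTrees = 1000, scalars = c(2, 4),
                       threshold = 0.01, seed = NULL, outDir = NULL,
                       missingLengthPolicy = c("error", "substitute"),
                       missingLengthValue = 0, keepSims = FALSE) {
  missingLengthPolicy <- match.arg(missingLengthPolicy)
  guideFile <- if (is.character(guide)) guide else NA_character_
  obsFile <- if (is.character(observed)) observed else NA_character_
  if (is.character(guide)) guide <- readNewickFile(guide)[[1L]]
  if (is.character(observed)) observed <- readNewickFile(observed)[[1L]]
  if (!setequal(guide$tip.label, observed$tip.label)) {
    d <- c(setdiff(guide$tip.label, observed$tip.label),
           setdiff(observed$tip.label, guide$tip.label))
    stop("guide and observed trees do not share a taxon set; differing: ",
         paste(d, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  scalarSeeds <- sample.int(.Machine$integer.max - 1L, length(scalars))
  simsByScalar <- lapply(seq_along(scalars), function(j)
    simulateGeneTrees(guide, nTrees = nTrees, scalar = scalars[j],
                      seed = scalarSeeds[j],
                      missingLengthPolicy = missingLengthPolicy,
                      missingLengthValue = missingLengthValue))
  report <- concordanceReport(observed, guide, simsByScalar,
                              threshold = threshold)
  if (is.null(outDir)) return(report)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  annotated <- annotateTree(observed, report)
  writeNewick(annotated, file.path(outDir, "annotated.nwk"))
  writeReportTable(report, file.path(outDir, "report.tsv"))
  if (keepSims) {
    for (s in simsByScalar)
      writeNewick(simTrees(s),
                  file.path(outDir, sprintf("sims_x%s.nwk",
                                            .fmtScalar(scalarFactor(s)))))
  }
  manifest <- list(
    tool = "cytoConcord",
    version = as.character(utils::packageVersion("cytoConcord")),
    guide_file = guideFile,
    guide_md5 = if (is.na(guideFile)) NA else unname(tools::md5sum(guideFile)),
    observed_file = obsFile,
    observed_md5 = if (is.na(obsFile)) NA else unname(tools::md5sum(obsFile)),
    n_trees = nTrees,
    scalars = paste(scalars, collapse = ","),
    threshold = threshold,
    seed = if (is.null(seed)) NA else seed,
    missing_length_policy = missingLengthPolicy,
    missing_length_value = missingLengthValue,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeManifest(manifest, file.path(outDir, "manifest.txt"))
  invisible(report)
}

#' Write a run manifest as plain key=value lines
#'
#' @param params Named list of scalar parameters.
#' @param file Output path.
#' @export
writeManifest <- function(params, file) {
  stopifnot(is.list(params), !is.null(names(params)))
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    paste0(k, "=", if (is.null(v) || length(v) == 0L) "" else
      paste(format(v, trim = TRUE), collapse = ","))
  }, character(1L))
  writeLines(lines, file)
  invisible(file)
}

#' Read a key=value manifest
#'
#' @param file Path written by [writeManifest()].
#' @return Named character vector.
#' @export
readManifest <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  stats::setNames(vapply(kv, `[`, character(1L), 2L),
                  vapply(kv, `[`, character(1L), 1L))
}
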