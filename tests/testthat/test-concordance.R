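test_that("clade frequencies count split membership over the tree sample", {
  obs <- parseNewick("((A,B),(C,D));")  # split AB|CD
  ab <- parseNewick("((A,B),(C,D));")
  ac <- parseNewick("((A,C),(B,D));")
  ad <- parseNewick("((A,D),(B,C));")

  # self-concordance
  f <- cladeFrequencies(obs, rep(list(ab), 100))
  expect_equal(as.numeric(f), 1)

  # absence
  f0 <- cladeFrequencies(obs, rep(list(ac), 50))
  expect_equal(as.numeric(f0), 0)

  # enumerated mixture: 3x AB|CD, 5x AC|BD, 2x AD|BC
  sims <- c(rep(list(ab), 3), rep(list(ac), 5), rep(list(ad), 2))
  expect_equal(as.numeric(cladeFrequencies(obs, sims)), 0.3)

  # quartet sum rule: the three resolved splits partition the sample
  total <- as.numeric(cladeFrequencies(obs, sims)) +
    as.numeric(cladeFrequencies(ac, sims)) +
    as.numeric(cladeFrequencies(ad, sims))
  expect_equal(total, 1)
})

test_that("frequencies are invariant to rerooting either side", {
  guide <- simulateGuideTree(8, seed = 5, meanLength = 0.8)
  sims <- simulateGeneTrees(guide, nTrees = 120, scalar = 2, seed = 6)
  obs <- makeObservedTree(guide, "pure_ils", seed = 9)
  f <- cladeFrequencies(obs, sims)
  obsR <- ape::root(obs, outgroup = "T0005", resolve.root = TRUE)
  fR <- cladeFrequencies(obsR, sims)
  expect_equal(sort(unname(f)), sort(unname(fR)))
  simsR <- lapply(simTrees(sims), ape::root, outgroup = "T0002",
                  resolve.root = TRUE)
  fSR <- cladeFrequencies(obs, simsR)
  expect_equal(f[names(f)], fSR[names(f)])
})

test_that("tip-set mismatches are reported with the differing taxa", {
  obs <- parseNewick("((A,B),(C,D));")
  bad <- parseNewick("((A,B),(C,E));")
  expect_error(cladeFrequencies(obs, list(bad)), "E")
  expect_error(cladeFrequencies(obs, list(bad)), "D")
})

test_that("the ILS-plausibility rule uses <= threshold under every scalar", {
  expect_equal(classifyBranch(c("2" = 0.29, "4" = 0.29))$combined,
               "ILS-plausible")
  expect_equal(classifyBranch(c("2" = 0.009, "4" = 0.001))$combined,
               "introgression-candidate")
  # a tie at the boundary is a candidate: the rule is "at most 1%"
  expect_equal(classifyBranch(c("2" = 0.01, "4" = 0.01))$combined,
               "introgression-candidate")
  # candidate under one scalar only: per-scalar verdicts disagree, the
  # combined verdict stays ILS-plausible
  v <- classifyBranch(c("2" = 0.017, "4" = 0.01))
  expect_equal(unname(v$perScalar),
               c("ILS-plausible", "introgression-candidate"))
  expect_equal(v$combined, "ILS-plausible")
  expect_error(classifyBranch(numeric(0)), "at least one")
})

test_that("reports cover every nontrivial branch and flag nuclear conflicts", {
  guide <- simulateGuideTree(12, seed = 13, lengthDistribution = "fixed",
                             fixedLength = 2)
  obs <- applyChloroplastCapture(guide, donor = "T0001", recipient = "T0008")
  sims <- lapply(c(2, 4), function(s)
    simulateGeneTrees(guide, nTrees = 300, scalar = s, seed = 40 + s))
  rep <- concordanceReport(obs, guide, sims)
  tab <- reportTable(rep)
  expect_equal(nrow(tab), 12 - 3)
  expect_named(tab, c("bipartition", "n_trees", "freq_x2", "freq_x4",
                      "conflicts_nuclear", "classification"))
  expect_true(all(tab$n_trees == 300))
  # the captured pair is a new split: conflicting and (here) a candidate
  capRow <- tab[tab$bipartition == "T0001,T0008", ]
  expect_equal(nrow(capRow), 1)
  expect_true(capRow$conflicts_nuclear)
  expect_equal(capRow$classification, "introgression-candidate")
  # splits shared with the guide tree are not conflicts
  guideKeys <- treeBipartitions(guide, taxa = rep@taxa)
  expect_equal(tab$conflicts_nuclear, !(rep@keys %in% guideKeys))
})

test_that("annotation writes per-scalar percentages with one decimal", {
  obs <- parseNewick("((A,B),(C,D));")
  mk <- function(freq2, freq4) {
    keys <- treeBipartitions(obs)
    tab <- data.frame(bipartition = "C,D", n_trees = 1000L,
                      freq_x2 = freq2, freq_x4 = freq4,
                      conflicts_nuclear = FALSE,
                      classification = "ILS-plausible")
    new("ConcordanceReport", table = tab, keys = as.character(keys),
        taxa = sort(obs$tip.label), scalars = c(2, 4), threshold = 0.01,
        nTrees = 1000L)
  }
  lab <- function(r) setdiff(unique(annotateTree(obs, r)$node.label), "")
  expect_equal(lab(mk(0.074, 0.026)), "7.4/2.6")
  expect_equal(lab(mk(1, 1)), "100.0/100.0")
  expect_equal(lab(mk(0, 0)), "0.0/0.0")
  # the annotated Newick carries the label exactly once (the AB|CD split is
  # one branch even though two rooted nodes display it)
  out <- writeNewick(annotateTree(obs, mk(0.074, 0.026)))
  expect_equal(length(gregexpr("7.4/2.6", out, fixed = TRUE)[[1]]), 1)
})
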