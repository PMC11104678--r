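test_that("synthetic guide trees have the promised shape", {
  g <- simulateGuideTree(10, seed = 1, lengthDistribution = "fixed",
                         fixedLength = 1.0)
  expect_length(treeBipartitions(g), 7)  # n - 3 unrooted internal edges
  internal <- g$edge[, 2] > 10
  expect_true(all(g$edge.length[internal] == 1.0))
  expect_true(all(is.na(g$edge.length[!internal])))  # terminal CU absent
  expect_true(all(grepl("^T\\d{4}$", g$tip.label)))
  expect_false(anyDuplicated(g$tip.label) > 0)

  # determinism and distinctness across seeds
  expect_identical(writeNewick(simulateGuideTree(10, seed = 1,
    lengthDistribution = "fixed", fixedLength = 1.0)), writeNewick(g))
  gExp <- simulateGuideTree(30, seed = 2, meanLength = 0.7)
  expect_true(all(gExp$edge.length[gExp$edge[, 2] > 30] >= 0))
  expect_error(simulateGuideTree(3), ">= 4")

  # the study-scale tree is cheap to generate
  elapsed <- system.time(simulateGuideTree(124, seed = 3))["elapsed"]
  expect_lt(elapsed, 1)
})

test_that("the chloroplast-capture move regrafts the recipient by the donor", {
  tr <- parseNewick("((A,B),(C,D));")
  cap <- applyChloroplastCapture(tr, donor = "C", recipient = "A")
  keys <- treeBipartitions(cap, taxa = sort(tr$tip.label))
  wanted <- treeBipartitions(parseNewick("((A,C),(B,D));"),
                             taxa = sort(tr$tip.label))
  expect_true(all(as.character(wanted) %in% as.character(keys)))
  expect_error(applyChloroplastCapture(tr, donor = "A", recipient = "A"),
               "disjoint")
  expect_error(applyChloroplastCapture(tr, donor = c("A", "C"),
                                       recipient = "B"), "not a clade")
  expect_error(applyChloroplastCapture(tr, donor = "Z", recipient = "A"),
               "unknown tip")

  # clade-to-clade capture
  big <- parseNewick("(((A,B),(C,D)),((E,F),(G,H)));")
  cap2 <- applyChloroplastCapture(big, donor = c("E", "F"),
                                  recipient = c("A", "B"))
  k2 <- treeBipartitions(cap2, taxa = sort(big$tip.label))
  sides <- bipartitionLabels(k2)
  expect_true(any(vapply(sides, function(x)
    setequal(x, c("A", "B", "E", "F")) || setequal(x, c("C", "D", "G", "H")),
    logical(1))))
})

test_that("the capture move is invertible at the topology level", {
  set.seed(19)
  for (i in 1:5) {
    g <- simulateGuideTree(12, seed = 100 + i)
    # recipient: a tip whose sister is also a tip, so the inverse move is
    # 'regraft back beside the old sister'
    sisters <- NULL
    for (tip in g$tip.label) {
      idx <- match(tip, g$tip.label)
      parent <- g$edge[g$edge[, 2] == idx, 1]
      sibs <- g$edge[g$edge[, 1] == parent, 2]
      other <- setdiff(sibs, idx)
      if (length(other) == 1 && other <= 12) {
        sisters <- c(tip, g$tip.label[other]); break
      }
    }
    expect_false(is.null(sisters))  # every binary tree has a two-tip cherry
    recipient <- sisters[1]; oldSister <- sisters[2]
    donor <- setdiff(g$tip.label, sisters)[1]
    moved <- applyChloroplastCapture(g, donor = donor, recipient = recipient)
    back <- applyChloroplastCapture(moved, donor = oldSister,
                                    recipient = recipient)
    expect_setequal(
      as.character(treeBipartitions(back, taxa = sort(g$tip.label))),
      as.character(treeBipartitions(g, taxa = sort(g$tip.label))))
  }
})

test_that("observed-tree scenarios encode their truth", {
  g <- simulateGuideTree(10, seed = 4, lengthDistribution = "fixed",
                         fixedLength = 50)
  # no ILS at 50 CU: the pure-ILS draw is topologically the guide tree
  obs <- makeObservedTree(g, "pure_ils", seed = 5)
  expect_setequal(as.character(treeBipartitions(obs)),
                  as.character(treeBipartitions(g)))
  expect_identical(writeNewick(makeObservedTree(g, "pure_ils", seed = 5)),
                   writeNewick(obs))

  capObs <- makeObservedTree(g, "capture", donor = "T0001",
                             recipient = "T0006")
  gk <- treeBipartitions(g, taxa = sort(g$tip.label))
  ck <- treeBipartitions(capObs, taxa = sort(g$tip.label))
  newSplits <- setdiff(as.character(ck), as.character(gk))
  expect_gt(length(newSplits), 0)
  donorRecipient <- paste(
    vapply(bipartitionLabels(ck, side = "smaller"), paste, character(1),
           collapse = ","))
  expect_true("T0001,T0006" %in% donorRecipient)
})

test_that("JC69 fixtures evolve and stamp gap features deterministically", {
  tr <- ape::rtree(6)
  a0 <- evolveJC69WithGaps(tr, nSites = 40, rate = 0, seed = 6)
  expect_equal(length(unique(apply(alignmentMatrix(a0), 1, paste,
                                   collapse = ""))), 1)
  blocks <- list(list(rows = NULL, cols = 11:20, char = "-"),
                 list(rows = c("t1", "t2"), cols = 31:35, char = "N"))
  a1 <- evolveJC69WithGaps(tr, nSites = 40, rate = 0.5, gapBlocks = blocks,
                           seed = 7)
  expect_true(all(alignmentMatrix(a1)[, 11:20] == "-"))
  expect_true(all(alignmentMatrix(a1)[c("t1", "t2"), 31:35] == "N"))
  expect_equal(alignmentMetadata(a1)$gapBlocks, blocks)
  a2 <- evolveJC69WithGaps(tr, nSites = 40, rate = 0.5, gapBlocks = blocks,
                           seed = 7)
  expect_identical(alignmentMatrix(a2), alignmentMatrix(a1))
  expect_error(evolveJC69WithGaps(tr, nSites = 0), "> 0")
})
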