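Package: cytoConcord
Title: Coalescent Simulation Tests for Cytonuclear Discordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether discordance between a nuclear species tree and an
    observed organellar (e.g. plastome) tree can be explained by incomplete
    lineage sorting alone. Simulates organellar gene trees under the neutral
    multispecies coalescent contained within a nuclear guide tree with branch
    lengths in coalescent units, after rescaling those lengths by an organellar
    inheritance scalar (x2 hermaphroditic, x4 dioecious); summarises per-branch
    concordance frequencies of the simulated trees on the observed tree; and
    flags branches whose observed relationship is too rare under pure lineage
    sorting as introgression (chloroplast-capture) candidates. Also provides
    the alignment-preparation operators used alongside such analyses
    (N-aware gap-threshold column masking, RY recoding, alignment statistics)
    and a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
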