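---
title: "Testing cytonuclear discordance: lineage sorting or plastome capture?"
author: "cytoConcord authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing cytonuclear discordance: lineage sorting or plastome capture?}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoConcord)
```

## The question

Organellar phylogenies — in plants, typically plastome trees — frequently
conflict with well-supported nuclear species trees. Two biological processes
dominate as explanations: **incomplete lineage sorting (ILS)**, the retention
of ancestral polymorphism across speciation events, and **introgression**, in
particular *chloroplast capture*, where hybridisation followed by
backcrossing fixes one lineage's plastome in another lineage. Telling the
two apart matters because they imply very different evolutionary histories.

cytoConcord implements a simulation-based test of the null hypothesis that
ILS alone explains an observed discordant branch. The plastome is inherited
as a single, non-recombining, haploid, uniparental linkage group, so its
gene tree is one draw from the multispecies coalescent (MSC) — but with an
effective population size a half (hermaphroditic taxa) or a quarter
(dioecious taxa) of the diploid nuclear genome's.

## The model and the decision rule

Let the nuclear **guide tree** be a rooted species tree whose internal
branch lengths are in coalescent units (CU; time divided by effective
population size in generations), as produced by summary methods such as
ASTRAL. The organellar genome's smaller effective population size is
equivalent to multiplying every CU branch length by an **inheritance
scalar** $s$: coalescence is $s$ times faster, so branches are effectively
$s$ times longer. We evaluate $s = 2$ (hermaphroditic) and $s = 4$
(dioecious) and report both.

Gene trees are drawn under the **contained (censored) coalescent**: one
lineage enters at each tip; within a species-tree branch of length $L$
carrying $k$ lineages, waiting times between coalescences are
$\mathrm{Exp}\!\left(\binom{k}{2}\right)$ in CU and each event merges a
uniformly random pair; lineages that fail to coalesce within $L$ are passed
to the parent branch, and the branch above the root is infinite. For a
rooted triplet $((A,B)\!:\!T, C)$ this yields the classical concordance
probability
$$P(\text{AB cherry}) \;=\; 1 - \tfrac{2}{3} e^{-sT},$$
which the test suite verifies against the simulator over a grid of $T$ and
$s$, together with a chi-square comparison against an independent
pairwise-clock oracle implementation on random 4–5-taxon trees.

Given 1000 simulated trees per scalar, every nontrivial bipartition of the
observed organellar tree receives a **concordance frequency** — the
fraction of simulated trees containing that split, compared in the unrooted
view over the full shared taxon set. The decision rule is deliberately
simple: if the observed relationship occurred in **at most 1%** of the
simulations, ILS is considered an unlikely sole explanation and the branch
is flagged as an *introgression candidate*. The comparison is an exact
`<=` on the reported fraction (a branch exactly at 1% is flagged), and the
combined verdict requires the rule to hold under **both** scalars;
per-scalar frequencies are always reported so users may apply a stricter
convention.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `nTrees` | 1000 | simulated gene trees per scalar; the Monte Carlo error of a frequency $p$ is $\sqrt{p(1-p)/1000}$, i.e. ~0.3% near the 1% threshold |
| `scalars` | 2, 4 | inheritance scalars (hermaphroditic / dioecious) |
| `threshold` | 0.01 | ILS-rejection threshold on the simulated frequency |
| `missingLengthPolicy` | `"error"` | missing *internal* CU lengths abort the run; `"substitute"` replaces them with `missingLengthValue` (default 0 CU, the ILS-maximising, conservative choice) |
| terminal lengths | 0 CU | with one sampled allele per species no coalescence can happen in a terminal branch, so absent terminal lengths (the rule in ASTRAL output) are immaterial |

Polytomies in the guide tree are treated as hard radiations: all child
lineages enter the parent branch together. Gene-tree branch lengths are
reported in rescaled CU on a shared depth axis but are informational only —
every downstream computation consumes topology.

## Reproducibility and numerical choices

A master seed spawns one derived seed per simulated tree, so run `i` of
`n` is identical to run `i` of `m > n` under the same master seed, and a
whole analysis is byte-reproducible (the report table and annotated Newick
are compared byte-for-byte in the tests). Newick output prints branch
lengths with 6 significant digits, more than any biological signal and
stable under round trips. Bipartitions are canonicalised as the side not
containing the lexicographically smallest taxon, making split identity
independent of rooting and tip order; when the two sides of a split are the
same size, display output uses the canonical side. A rooted tree displays
the split next to the root on two nodes; annotation labels it once.

## What the synthetic-data generator emulates — and what it does not

No real guide or plastome trees ship with the package; the generator stands
in for them. `simulateGuideTree()` produces a random birth-process topology
with i.i.d. exponential internal CU lengths (mean 1.0 by default) and
absent terminal lengths — mirroring the *shape* of an ASTRAL supercontig
species tree at the ~124-taxon scale of a typical subfamily-level study,
but not its depth structure: real coalescent-unit lengths correlate with
topology and with gene-tree error, and real studies have outgroups and
uneven sampling. `applyChloroplastCapture()` models capture purely
topologically (a subtree prune-and-regraft placing the recipient beside the
donor), not as a mixture of gene histories, because the decision rule only
ever sees the observed topology. `evolveJC69WithGaps()` produces toy JC69
alignments with gap/N blocks stamped at recorded coordinates; richer
substitution models would add nothing to what the alignment operators need
to demonstrate.

Passing tests on these synthetics therefore show that the machinery is
correct under the stated model — not that the 1% rule has any particular
error rate on real data, where gene-tree error, branch-length
underestimation and model violations all push the test toward conservatism.

The end-to-end harness fixes internal lengths at 2.0 CU and moves a
recipient across at least three species-tree edges. Those settings make
detection essentially certain: the capture split is astronomically rare
under the MSC, and the suite requires it to be flagged in at least 95% of
replicates. The mirror-image check — that discordant branches in pure-ILS
observed trees are *rarely* flagged — fails under the same settings, and
the failure is structural rather than an implementation artifact: when all
internodes are a uniform 2.0 CU, a genuinely ILS-generated discordant
split has expected simulated frequency $\tfrac{1}{3}e^{-2s}$ (≈0.6% at
$s=2$, ≈0.01% at $s=4$), which sits at or below the 1% threshold by
construction. Conditional on observing any discordance across uniformly
long internodes, the rule will almost always reject ILS. In real datasets
the rule is informative precisely because discordances concentrate on
*short* internodes, where simulated frequencies are far above 1%; the
suite keeps the uniform-length check in place (red) as an honest record of
this boundary of the method, rather than weakening the harness to hide it.

## The alignment operators

The package also ships the bespoke alignment-preparation steps used
alongside such analyses:

* `maskGappyColumns()` converts `N` to `-` (optionally) and removes every
  column whose gap fraction is **strictly greater** than 99% — equivalently,
  columns containing only missing data or autapomorphic insertions present
  in at most 1% of rows. A column at exactly the threshold is kept; the
  operation is idempotent and records kept-column indices for exact
  bookkeeping.
* `ryRecode()` collapses A,G to purine R and C,T to pyrimidine Y, leaving
  gaps and existing R/Y untouched; every other ambiguity code becomes `N`,
  since a code spanning both categories carries no purine/pyrimidine
  information (the information-conservative choice for codes the mapping
  does not define).
* `alignmentStats()` reports alignment length, per-sequence degapped
  lengths (characters that are neither `-` nor `N`) and the number of
  parsimony-informative sites — columns where at least two distinct
  unambiguous bases (A, C, G, T strictly; no ambiguity code is a state)
  each occur in at least two sequences. Under this definition an RY-recoded
  alignment has zero parsimony-informative sites, which is why the
  recoding's information loss is monotone by construction.

## A worked example

```{r example}
guide <- simulateGuideTree(20, seed = 101, lengthDistribution = "fixed",
                           fixedLength = 2)
observed <- makeObservedTree(guide, "capture",
                             donor = "T0004", recipient = "T0017")
report <- runIlsTest(guide, observed, nTrees = 1000, scalars = c(2, 4),
                     threshold = 0.01, seed = 202)
report
candidateBranches(report)
```

The capture-derived split (`T0004,T0017`) is absent or nearly absent from
the simulations under both scalars and is flagged; branches shared with the
guide tree sit near 100%.

## Problem sizes used in the shipped checks

The test suite runs the triplet law at 10,000 draws per configuration, the
oracle comparison on 20 random 4–5-taxon trees at 5,000 draws per
implementation, the capture/pure-ILS harness at 100 replicates of 12-tip
trees with 1000 simulated trees per scalar, and the study-scale pipeline on
a 124-tip guide tree (1000 trees × 2 scalars), which completes in well
under a minute on one CPU. The PIS counter is cross-checked against a
per-column brute force on 1,000 random alignments.

## Known limitations

* One allele per species; no migration, recombination or time-calibrated
  output.
* The test consumes a point estimate of the guide tree; uncertainty in CU
  branch lengths (and gene-tree error, which biases them downward) is not
  propagated — the 1% rule is conservative in that respect.
* Concordance is measured per bipartition, not per quartet, and no formal
  introgression test (D-statistics, networks) is attempted: a flagged
  branch is a *candidate*, not a demonstration of capture.
* trimAl-style heuristic trimming and ML tree inference are out of scope;
  only the threshold-masking trimmer is implemented here.
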