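---
title: "Methods: exact parsimony analysis of binary morphological characters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact parsimony analysis of binary morphological characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpclad)
```

mpclad implements a complete maximum-parsimony workflow for binary
morphological character matrices: Fitch scoring, exact branch-and-bound
search for *all* most-parsimonious trees (MPTs), heuristic search, strict
and majority-rule consensus, jackknife resampling, and ACCTRAN
ancestral-state mapping. It ships, as its worked data set, a published
20-taxon × 19-character matrix describing the oral secondary
mechanoreceptor cells of tunicates (the coronal organ and the
appendicularian circumoral ring) with a cephalochordate and three
vertebrates as outgroups. This vignette explains the models and the
numerical choices; the README shows the worked example.

## The scoring model

Characters are unordered binary (states 0/1) with unit weights. A cell is a
*state set*: `0` and `1` are singletons, while missing (`?`), inapplicable
(`-`) and polymorphic/uncertain (`0/1`) cells are all the full set {0, 1}.
During optimisation a full-set leaf is free to take whichever state is
cheapest — the standard treatment of missing data in parsimony software, and
the cheapest (hence most conservative) treatment of `0/1`, which we read as
uncertainty rather than as a polymorphism demanding both states. The
distinction between the three full-set codings is kept as a per-cell source
tag so NEXUS files round-trip exactly; it has no effect on any score.

The length of a tree is the minimum number of state changes over all
assignments of states to internal nodes, computed per character by the
Fitch intersection/union pass and summed. The implementation packs 32
binary characters into a 64-bit word, so a whole-tree score is a few dozen
word operations; correctness is tested against explicit enumeration of all
internal labelings on small trees and against an independent
implementation (phangorn) on random matrices.

Per-character bounds follow from counting unambiguous cells only: the
minimum conceivable steps are (number of observed states − 1), the maximum
is the count of cells carrying the minority state. From these the ensemble
consistency index CI = min/observed, retention index
RI = (max − observed)/(max − min) and rescaled consistency RC = CI·RI are
formed. **Convention:** CI includes *all* characters, informative or not,
because that is the convention under which the published value for the
bundled matrix (0.76 = 19/25) is arithmetically consistent; the
alternative value over informative characters only is always reported
alongside. A character is *informative* when at least two states are each
carried unambiguously by two or more taxa, *autapomorphic* when exactly one
unambiguous cell carries the minority state, *constant* otherwise;
full-set cells never count toward these tallies.

## Exact search

The branch-and-bound search grows trees by stepwise taxon addition. The
addition order is fixed before the search ("max–min"): a starting triple
maximising the three-taxon length, then repeatedly the taxon whose
cheapest insertion into a greedily grown reference tree is most expensive,
ties broken by matrix row order. The reference tree also provides the
initial upper bound. Each partial tree is scored exactly, and a branch is
pruned when its length plus an admissible lower bound exceeds the current
optimum; the bound adds one step for every character for which some
not-yet-added taxon carries an unambiguous state absent from the partial
tree's unambiguous states. Because each unrooted binary topology arises
from exactly one insertion sequence under a fixed order, the archive of
full-length trees that tie the optimum is the complete, duplicate-free MPT
set. Ties are never pruned (the bound test uses strict inequality), so
completeness does not depend on the quality of the initial upper bound.
The search is deterministic. Equality of both the optimal length and the
complete optimal set with exhaustive enumeration is asserted on random
matrices of up to 8 taxa (enumeration is guarded to 10 taxa, where the
(2n−5)!! count reaches 2,027,025).

The heuristic search (used inside the jackknife, and to sanity-check the
exact search) runs a configurable number of random addition sequences;
each builds a tree by cheapest stepwise insertion and then descends by
first-improvement tree bisection-reconnection (TBR) swapping. All distinct
topologies tying the best length are archived, and swapping restarts from
every archived tree until the set is closed, emulating a
"retain all optimal trees" strategy. Topology identity is the set of
non-trivial bipartitions. An archive cap (`max_trees`) guards against tie
explosions on weakly structured resampled matrices; a hit of the cap is
flagged in the diagnostics.

## Consensus, support, and character mapping

Consensus trees are computed over non-trivial bipartitions, each stored
canonically as the side excluding the lexicographically smallest taxon.
Strict consensus keeps bipartitions at 100% frequency; majority rule keeps
those strictly above 50% (plain majority rule — no compatible-minority
grafting). Displays round frequencies to whole percentages; the tables
keep full precision.

Jackknife support deletes each character independently with probability
0.30 per replicate (redrawing in the degenerate all-deleted case), runs
the heuristic search on the reduced matrix, and credits a bipartition when
it appears in the strict consensus of the replicate's optimal trees; a
fixed-deletion-count mode and fractional (per-tree) weighting are provided
as options. The defaults — 30% deletion, 10 addition replicates per
search, TBR — mirror the published protocol for the bundled matrix. The
published analysis quotes both 1000 replicates (methods) and 100
(figure); both are runnable, and neither is treated as uniquely correct.
Internally taxa are processed in sorted label order, making support values
invariant to the row order of the input matrix under a fixed seed.

ACCTRAN reconstruction uses a unit-cost dynamic programme over state
assignments (leaf state sets respected) on the display rooting: the tree
is rooted on the edge separating the outgroups from the ingroup whenever
such an edge exists, otherwise on the first outgroup's pendant edge with a
warning. The top-down pass prefers a change over retention whenever both
are equally parsimonious, which places changes as close to the root as
possible; root-state ties resolve toward the state supported by the
outgroup-side subtree, then to state 0. Full-set leaves never generate a
change on their own pendant edge. By construction the number of
reconstructed changes equals the Fitch step count — asserted matrix-wide
in the tests. Transformations are keyed by the descendant taxon set of
their branch; `unambiguous_changes()` intersects these keys across an
entire tree set, so a retained transformation occurs identically in every
optimal tree.

## The synthetic-data generator

`simulate_tree()` draws uniform random unrooted binary topologies by
sequential random edge attachment. `simulate_matrix()` evolves each
character from a uniform root state with an independent per-edge flip
probability (a symmetric two-state Mk-type process, no rate
heterogeneity), then overwrites cells uniformly at random as missing,
inapplicable or ambiguous at the requested fractions. The process runs
over the unrooted tree's 2n−3 edges (evolving from an arbitrary leaf), so
each edge carries the flip probability exactly once — rooting the process
inside an edge would silently double that edge's rate. Defaults are a
flip probability of 0.05 and no cell corruption. The tree-recovery
experiment in the tests uses 0.02 with 50 characters on 8 taxa against a
90%-recovery benchmark; measured recovery there is a little lower (the
tests record 89 of 100 seeded runs, and in every miss the generating
topology is genuinely one or two steps longer than the optimum), which is
worth knowing when choosing simulation settings: at this signal level
parsimony is misled in a non-negligible fraction of data sets. What the
generator deliberately does **not** emulate is the hierarchical structure
of real inapplicable coding (in the bundled matrix, characters about
monociliary cells are inapplicable for multiciliated taxa as a block);
corruption here is independent across cells. Tests passing on synthetic
data therefore validate the machinery, not the biological realism of any
particular missingness pattern. `known_answer_fixture()` (guarded to 9
taxa) pairs a simulated matrix with its complete optimal tree set found by
exhaustive enumeration and is the oracle for the search tests.

## The bundled matrix and the published numbers

The bundled data set is the printed source table, transcribed cell for
cell, including a `?` for *Pyrosoma atlanticum* character 15, the
`0/1` cell for *Oikopleura dioica* character 6, and the printed
inapplicable cells. The printed *O. dioica* row ends one cell short;
character 19 is coded missing, and `coronal_matrix(oikopleura_19 = "1")`
(the state suggested by the text, which describes the species' circumoral
ring as continuous) exists for sensitivity analysis.

Running the exact search on this printed table gives an optimal length of
26 with 30,510 distinct MPTs (CI 0.73, RC 0.64), whereas the original
publication reports 25, 80 trees, CI 0.76 and rCI 0.68 from the archived
(TreeBase) version of the matrix. The difference is a property of the
printed table, not of the algorithms: an independent implementation
(phangorn) finds the same optimum on the same input, and this package's
search is exhaustively verified against enumeration at small sizes. A
scan of every single-cell edit of the printed table finds several variants
that reach length 25 — four of which also match the published CI, RC and
character classification — but none yields 80 optimal trees, so the
archived matrix must differ from the printed one in more than one cell.
The character-19 sensitivity variants leave the optimum at 26 (`?` or
`1`) or raise it to 27 (`0`). `reproduce_analysis()` therefore reports
computed and published values side by side rather than reconciling them;
the classification counts (16 informative, 2 autapomorphies for
*O. dioica*, 1 for *D. listerianum*), the published clades of the
majority-rule consensus, and all four published stem-lineage
transformations (characters 1, 3, 4 and 9) do reproduce exactly on the
printed table, the latter on every one of the 30,510 optimal trees.

## Degenerate inputs and problem sizes

Matrices must keep at least two taxa after pruning; searches need three
(exact) or four (heuristic, TBR) taxa; bipartition bookkeeping needs
four leaves; an observed length of zero makes CI undefined and is reported
as 1 with a warning; consensus input must share one leaf set, and the
offending tree is named otherwise. Topology enumeration refuses more than
10 leaves, the known-answer oracle more than 9, and the bit-packed
engines more than 64 taxa (a uint64 bipartition mask per split).

The test suite sizes its simulations to stay exhaustive where an oracle is
exhaustive: 6–8 taxa for enumeration-backed search checks, 200 jackknife
replicates for the support-recovery property, 100 seeded simulations for
topology recovery, and the full 30,510-tree optimal set for the consensus
and transformation claims about the bundled matrix.

## Limitations

Only unordered binary characters with unit weights are supported — no
multistate, ordered, weighted or molecular data, no Sankoff costs, no
implied weighting, and no bootstrap or decay indices. ACCTRAN is the only
reconstruction exposed; reconstruction is never performed on the
(multifurcating) consensus itself, only on binary trees. The jackknife's
archive cap makes per-replicate optimal sets potentially incomplete on
very flat resampled landscapes; support values there are conservative
approximations of the retain-all ideal.
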