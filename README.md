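# mpclad

Maximum-parsimony cladistics for binary morphological character matrices.

`mpclad` is built for the kind of analysis morphologists run on small,
hand-coded data sets: a matrix of presence/absence characters over a few
dozen taxa, with missing (`?`), inapplicable (`-`) and uncertain (`0/1`)
cells, analysed under equal-weights Fitch parsimony. It provides

- NEXUS matrix I/O that preserves the missing/inapplicable/polymorphic
  distinction through round trips, and Newick tree I/O (via ape);
- exact **branch-and-bound** search returning *all* most-parsimonious
  trees, plus a heuristic search (random addition sequences + TBR
  swapping, retaining all optimal trees);
- ensemble fit statistics (CI, RI, RC) and per-character classification
  (constant / autapomorphic / parsimony-informative);
- **strict** and **50% majority-rule consensus** trees with bipartition
  frequencies;
- **jackknife** support by random character deletion with per-replicate
  heuristic searches;
- **ACCTRAN** ancestral-state reconstruction and per-branch apomorphy
  lists, including the transformations shared by every optimal tree;
- a binary-character simulator (uniform random trees, symmetric
  per-edge flip model, injected missing/inapplicable/ambiguous cells)
  with an exhaustive known-answer oracle for validation.

The package ships a published 20-taxon × 19-character matrix of chordate
oral secondary-sensory-cell morphology (tunicate coronal organs and the
appendicularian circumoral ring, with amphioxus and three vertebrates as
outgroups) as `coronal_matrix()` and reproduces its full analysis.

## The model in brief

For a character with state set assignments at the leaves, the Fitch length
of a tree is the minimum number of 0↔1 changes over all internal-node
labelings; cells coded `?`, `-` or `0/1` carry the full state set {0,1}
and resolve freely. For observed total length L, per-character minima m_i
and maxima M_i (counted from unambiguous cells only),

    CI = Σm_i / L,   RI = (ΣM_i − L) / (ΣM_i − Σm_i),   RC = CI × RI.

Branch and bound enumerates taxon-addition sequences with an admissible
per-character lower bound, so the returned tree set is provably the
complete set of optimal unrooted binary topologies.

## Worked example

```r
library(mpclad)

m <- coronal_matrix()
classify_characters(m) |> dplyr::count(status)
#> # A tibble: 2 × 2
#>   status            n
#>   <chr>         <int>
#> 1 autapomorphic     3
#> 2 informative      16

res <- branch_and_bound(m)
res
#> <mp_search:branch-and-bound> 30510 optimal tree(s) of length 26
#>   CI 0.73  RI 0.88  RC 0.64
```

Sixteen characters are parsimony-informative; the three autapomorphies
(two for *Oikopleura dioica*, one for *Diplosoma listerianum*) match the
published classification exactly. The exact search on this printed matrix
finds 30,510 equally parsimonious trees of length 26 — see "A note on the
published numbers" below.

```r
cons <- majority_rule(res$trees)
head(tidy(cons)[, c("bipartition", "frequency")], 4)
#> # A tibble: 4 × 2
#>   bipartition                                                    frequency
#>   <chr>                                                              <dbl>
#> 1 Botrylloides leachi, Botryllus schlosseri                            100
#> 2 Danio rerio, Lethenteron camtschaticum                               100
#> 3 Molgula socialis, Pyura stolonifera                                  100
#> 4 Molgula socialis, Polyandrocarpa zorritensis, Pyura stolonife…       100
```

The consensus recovers the published clades: a monophyletic
Stolidobranchiata, the solitary styelid + molgulid + pyurid group,
Vertebrata, Enterogona plus *Oikopleura* (100%), and a monophyletic
Tunicata (68%). Character transformations shared by **every** optimal
tree include the published stem-lineage changes:

```r
apo <- unambiguous_changes(res$trees, m, outgroup = coronal_outgroups())
subset(apo, character %in% c(1, 3, 4, 9),
       select = c(character, from, to, branch))
#> # A tibble: 4 × 4
#>   character  from    to branch
#>       <int> <int> <int> <chr>
#> 1         1     1     0 Botrylloides leachi, Botryllus schlosseri, Molgula so…
#> 2         3     0     1 Molgula socialis, Polyandrocarpa zorritensis, Pyura s…
#> 3         4     0     1 Ascidiella aspersa, Chelyosoma productum, Ciona intes…
#> 4         9     0     1 Botrylloides leachi, Botryllus schlosseri
```

Row 1 is the Stolidobranchiata stem (more than one sensory-cell type is
lost), row 2 the solitary-styelid + molgulid + pyurid stem (biciliated
cells arise), row 3 the Enterogona + *Oikopleura* stem (multiciliated
cells arise) and row 4 the botryllid stem (eccentric cilium position).

Jackknife support (30% deletion, heuristic searches with 10 random
addition sequences) and the full juxtaposed report:

```r
jk  <- jackknife(m, replicates = 100, seed = 1)
rep <- reproduce_analysis(seed = 1, out_dir = "results/report")
```

(The full report takes roughly a quarter of an hour on one CPU; nearly all
of it is the 100-replicate jackknife and the transformation intersection
over the 30,510 optimal trees. The exact search itself takes ~12 seconds.)

A thin command-line wrapper over the same functions lives at
`inst/scripts/mpclad.R` (subcommands `search`, `consensus`, `jackknife`,
`trace`, `simulate`, `reproduce`).

## A note on the published numbers

The original publication reports length 25, 80 equally parsimonious
trees, CI 0.76 and rCI 0.68. Those values derive from the archived
(TreeBase) version of the matrix, which differs from the printed source
table: on the printed table — transcribed here cell for cell — the
optimum is 26 with 30,510 optimal trees (CI 0.73, RC 0.64), a result
confirmed by an independent implementation (phangorn) on the same input.
No single-cell edit of the printed table yields the published tree count.
The package keeps the printed table as its data set and reports both sets
of numbers side by side (`reproduce_analysis()`); the published character
classification, consensus clades and stem-lineage transformations all
reproduce exactly on the printed table. The vignette documents the
analysis behind this discrepancy.

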