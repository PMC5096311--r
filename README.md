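# gosimtab

Fast Gene Ontology (GO) semantic similarity for R, built on precomputed
lookup tables.

## The problem

Semantic similarity between GO terms — and the gene functional similarity
derived from it — underpins gene clustering, interaction prediction and
disease-gene prioritisation. The standard measures all need quantities that
live deep in the GO graph (common ancestors, information content, depths,
Wang S-values, annotation closures), and computing them by graph traversal
for every query makes genome-scale batches (10⁶+ pairs) painfully slow.

`gosimtab` separates the work into two steps:

1. **Build** — compile the ontology (OBO) and an annotation corpus (GAF)
   once into per-method lookup tables: information content, longest-path
   depth, per-term Wang S-value maps, ancestor sets, and per-gene
   annotation closures.
2. **Query** — answer term–term and gene–gene similarity from the tables
   alone. The graph object is never touched again; a suite of naive
   repeated-traversal reference implementations certifies that the fast
   path returns *identical* results.

## Measures

For terms $t_1, t_2$ with most informative common ancestor (MICA), using
$IC(t) = -\ln p(t)$ where $p(t)$ is the annotation-closure frequency of $t$
in the corpus:

| measure | definition |
|---|---|
| Resnik | $IC(\mathrm{MICA})$ |
| Lin | $2\,IC(\mathrm{MICA}) / (IC(t_1) + IC(t_2))$ |
| Jiang–Conrath | $1 - (IC(t_1) + IC(t_2) - 2\,IC(\mathrm{MICA}))$ |
| Pekar–Staab | $\delta(t_a, r) / (\delta(t_a, r) + \delta(t_1, r) + \delta(t_2, r))$ with $t_a$ the deepest common ancestor, $\delta$ the longest-path depth |
| Wang | $\sum_{t \in T_A \cap T_B} (S_A(t) + S_B(t)) / (SV(A) + SV(B))$ |
| simUI | $\lvert A(g_1) \cap A(g_2)\rvert / \lvert A(g_1) \cup A(g_2)\rvert$ over annotation closures |
| simGIC | $\sum_{t \in \cap} IC(t) / \sum_{t \in \cup} IC(t)$ over annotation closures |

Wang S-values decay along edges by semantic contribution factors
(defaults: `is_a` 0.8, `part_of` 0.6). Gene-level scores for the pairwise
measures combine the term matrix by `max`, `avg`, or best-match average
(`bma`). See the methods vignette (`vignettes/gosimtab-methods.Rmd`) for
assumptions, variants and numerical choices.

## Worked example

The seven-term cellular-component graph around *intracellular
membrane-bounded organelle* (GO:0043231) ships with the package:

```r
library(gosimtab)
dag <- organelle_dag()
ann <- annotation_set(
  data.frame(gene = c("gA", "gB"), term = c("GO:0043227", "GO:0005622")),
  namespace = "CC")
tab <- build_tables(dag, ann)

tab$svalues[["GO:0043231"]]
#> GO:0005575 GO:0005622 GO:0005623 GO:0043226 GO:0043227 GO:0043229 GO:0043231
#>      0.512      0.480      0.288      0.640      0.800      0.800      1.000

tab$sv[c("GO:0043227", "GO:0005622")]
#> GO:0043227 GO:0005622
#>       2.44       2.08

sim_wang("GO:0043227", "GO:0005622", tab)
#> [1] 0.2477876
```

Reading the numbers: each S-value is the contribution of an ancestor to the
semantics of GO:0043231, decaying by 0.8 per `is_a` edge and 0.6 per
`part_of` edge along the best path. The semantic values 2.44 and 2.08 are
the S-value sums of *membrane-bounded organelle* and *intracellular*; their
only shared ancestor is the root, contributing 0.64 + 0.48 = 1.12, so the
Wang similarity is 1.12 / (2.44 + 2.08) ≈ 0.25 — a weakly related pair.

The same queries run from a saved table directory via the CLI:

```sh
Rscript inst/scripts/gosimtab build --obo go.obo --gaf ann.gaf --namespace CC --out tables/
Rscript inst/scripts/gosimtab termsim --tables tables/ --measure wang --pairs pairs.tsv --out out.tsv
Rscript inst/scripts/gosimtab genesim --tables tables/ --measure simgic --pairs gpairs.tsv --out out.tsv
Rscript inst/scripts/gosimtab simulate --terms 500 --genes 100 --seed 1 --out-prefix sim
```

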