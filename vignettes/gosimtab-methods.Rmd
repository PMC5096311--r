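---
title: "Methods: table-backed GO semantic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: table-backed GO semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gosimtab)
```

## The model

The Gene Ontology is three directed acyclic graphs (biological process,
molecular function, cellular component), with child-to-parent edges typed
by relation (`is_a`, `part_of`, and others such as `regulates`). Semantic
similarity between two terms, and the gene functional similarity derived
from the terms annotating two genes, are defined on quantities of this
graph:

* **Information content.** $IC(t) = -\ln p(t)$, where $p(t)$ is the
  annotation-closure frequency of $t$: the number of annotations falling on
  $t$ or any descendant, divided by the same quantity at the namespace root
  (so $p(\mathrm{root}) = 1$ exactly and $IC(\mathrm{root}) = 0$).
* **Depth.** The longest-path edge count from the root down to a term.
* **Wang S-values.** Within the ancestor sub-DAG of a term $A$,
  $S_A(A) = 1$ and $S_A(t) = \max \{ w_e \cdot S_A(t') \}$ over children
  $t'$ of $t$ in the sub-DAG, where $w_e$ is the semantic contribution
  factor of the edge; $SV(A) = \sum_{t} S_A(t)$.
* **Annotation closures.** $A(g)$ is the union of the ancestor sets of the
  gene's direct annotations (true-path rule).

Five pairwise term measures (Resnik, Lin, Jiang–Conrath, Pekar–Staab,
Wang), three gene-level combination rules (max, average, best-match
average) and two group-wise gene measures (simUI, simGIC) are implemented
on top of these quantities.

The package's central design is a **two-step workflow**: `build_tables()`
performs one topological pass per table over the graph and stores keyed
lookup structures (R named vectors and lists, giving constant-effort keyed
access); all query functions consume tables only. The separation is
enforced by the interface — no query function accepts the graph — and the
test suite verifies both that queries survive deletion of the graph object
and that the fast path agrees with naive per-query traversal to within
1e-12 on hundreds of randomised instances (in practice the agreement is
exact, since both paths perform the same arithmetic on the same operands).

## Tunable parameters

* **Semantic contribution factors** (`semantic_factors()`): unitless decay
  weights per relation, strictly inside $(0, 1)$; defaults `is_a` = 0.8,
  `part_of` = 0.6, the values conventional for the Wang measure. Relations
  without a factor (e.g. `regulates`) are retained in the graph and count
  for plain ancestor queries, but are excluded from S-value propagation —
  the measure defines decay only for weighted relations, and a relation
  with no weight cannot contribute semantics. The factors are recorded in
  the table manifest and a table directory built with different factors is
  refused at load time.
* **Closure counting mode** (`counting`): `"literal"` (default) sums direct
  annotation counts over a term and all strict descendants, so a gene
  annotated to two descendants contributes twice; `"distinct"` counts each
  gene once. The literal sum is the classical frequency formula as usually
  written; the distinct mode is offered because the literal sum
  double-counts multiply-annotated genes. Both satisfy monotonicity along
  edges; IC values differ slightly between them, so the mode is recorded in
  the manifest.
* **Evidence filter** (`parse_gaf(evidence_exclude=)`): empty by default —
  all evidence codes including IEA are kept. Rows with `NOT` qualifiers are
  always dropped.
* **Measure variants**: `jiang_clamp` (default off) clamps negative
  Jiang–Conrath scores to zero; the unclamped form is one minus a distance
  and genuinely unbounded below. `pekar_variant` selects `"as_printed"`
  (default; all three path lengths measured from the root, which is exactly
  what a depth table supports) or `"classic"` (distances from the two terms
  to the common ancestor itself, requiring the per-term ancestor-distance
  maps built alongside the depth table). The two variants coincide whenever
  the common ancestor lies on a longest root path of both terms; both are
  kept because the depth-only form and the textual definition of the
  measure differ, and neither is asserted as canonical.

## Numerical and policy choices

* **Logarithm base**: natural log, recorded in the manifest
  (`log_base=natural`). Any fixed base rescales all ICs uniformly; Lin,
  Jiang (through its distance) and simGIC are affected by base only through
  this common rescaling of their numerators and denominators, and Resnik
  values are simply in nats.
* **Terms with zero closure count** have no defined IC and are *absent*
  from the IC table; IC-based queries touching them raise an error naming
  the term rather than returning a sentinel value. In a consistent build
  this cannot happen for gene queries (every direct annotation has a
  positive count, and closure counts are monotone towards the root);
  `sim_gic(missing_ic = "zero")` exists for deliberately mixed table sets.
* **Tie-breaks**: all argmax choices over ancestors (most informative
  common ancestor, deepest common ancestor) break ties by lexicographically
  smallest term ID, making every output deterministic. An identical term
  pair short-circuits to itself — a term is its own most informative common
  ancestor even when an ancestor happens to tie its IC.
* **Self-similarity**: Lin and Wang return exactly 1 for $t = t$ by
  short-circuit, avoiding a floating-point quotient of equal sums.
* **Degenerate Pekar denominators** (root against root) return 0.
* **Serialisation**: tables persist as sorted plain TSV with reals printed
  at 17 significant digits, which round-trips IEEE doubles exactly; the
  suite asserts bit-for-bit equality after save/load and byte-identical
  output across rebuilds. The manifest stores namespace, factors, counting
  mode and row counts; loads verify row counts (truncation detection) and
  factor agreement. Besides the per-term tables, the directory carries the
  per-gene *direct* term sets and the per-term ancestor-distance maps: the
  gene-level pairwise rules operate on direct sets and the classic
  Pekar variant needs ancestor distances, and without them a query run
  started from a table directory would need the GAF or the graph again.
* **Gene-level pairwise similarity** uses the genes' *direct* annotation
  sets, not closures: the term-matrix inputs are the genes' annotation
  lists, and closures would force every matrix to contain the root and
  inflate every score. The group-wise measures use closures, as their
  graph-based definitions intend; `mode = "direct"` is available for
  comparison. Best-match average is
  $(\sum_i \max_j M_{ij} + \sum_j \max_i M_{ij}) / (m + n)$ — symmetric by
  construction.

## The synthetic generator

`random_dag()` orders terms and samples each term's parents uniformly from
its predecessors — acyclicity and a single root are guaranteed by
construction — labelling each edge `part_of` with a configurable
probability. `random_annotations()` gives each gene
$\max(1, \mathrm{Poisson}(\lambda))$ direct terms sampled uniformly.
Both are byte-deterministic under their seed, and both emit standard OBO /
GAF text so the synthetic path exercises the real parsers.

These graphs emulate the *structural* properties the algorithms depend on
(multiple inheritance, mixed relation types, shared ancestors, multiply
annotated genes). They do not emulate GO's realism: term-count and depth
distributions, the strong depth–frequency correlation of real corpora, or
evidence-code composition. Passing the equivalence suite therefore shows
that the table-backed path computes the *same function* as graph traversal
on arbitrary valid inputs — which transfers to real GO releases — but says
nothing about biological interpretation of the scores on any particular
corpus.

## Problem sizes in the test suite

The randomised equivalence experiment uses 100 generated instances of up
to 50 terms and 40 genes with at most 3 parents per term, comparing every
measure (and both Pekar variants) against memoisation-free traversal; the
batch-query check runs 10⁴ term pairs against tables built from a 300-term
instance. These sizes keep the naive oracle — which deliberately
re-traverses the graph on every call, with no memoisation inside the
S-value recursion — comfortably tractable while exercising diamond
structures, multiple root paths and mixed-relation propagation densely.

## Known limitations

* One namespace per table set; cross-namespace similarity is undefined and
  rejected (the three ontologies are orthogonal).
* OBO parsing covers the flat-file subset the graph needs (`id`, `name`,
  `namespace`, `is_a`, `relationship`, `alt_id`, `is_obsolete`); OWL,
  intersections and cross-products are out of scope.
* The literal counting mode reproduces the classical closure-frequency
  formula including its double counting; corpus-level probabilities are
  therefore not frequencies of distinct genes unless `distinct` is chosen.
* Tables are rebuilt, not incrementally updated, on ontology change — a
  build is a few topological passes and is cheap at GO scale.
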