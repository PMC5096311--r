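# shared fixtures built in code

# corpus used throughout: three genes on the 7-term example DAG
fixture_annotations <- function() {
  annotation_set(
    data.frame(gene = c("gA", "gB", "gC"),
               term = c("GO:0043227", "GO:0005622", "GO:0005575"),
               stringsAsFactors = FALSE),
    namespace = "CC")
}

fixture_tables <- function(...) {
  build_tables(organelle_dag(), fixture_annotations(), ...)
}

# one random (dag, annotation) instance; deterministic in `seed`
random_instance <- function(seed, n_terms = NULL, n_genes = NULL) {
  with_seed_local(seed, {
    if (is.null(n_terms)) n_terms <- sample(5:50, 1)
    if (is.null(n_genes)) n_genes <- sample(3:40, 1)
    mp <- sample(1:3, 1)
    pof <- stats::runif(1)
    mean_terms <- stats::runif(1, 1, 3)
    dag <- random_dag(n_terms, max_parents = mp, part_of_fraction = pof,
                      seed = seed * 13L + 7L)
    ann <- random_annotations(dag, n_genes, mean_direct_terms = mean_terms,
                              seed = seed * 17L + 3L)
    list(dag = dag, ann = ann)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force reflexive ancestor closure by plain DFS, independent of
# ancestors()'s BFS implementation
dfs_ancestors <- function(dag, term) {
  out <- character()
  visit <- function(t) {
    if (t %in% out) return(invisible())
    out <<- c(out, t)
    for (p in names(dag$parents_of[[t]])) visit(p)
  }
  visit(term)
  sort(out)
}
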