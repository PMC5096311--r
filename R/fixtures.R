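# fixtures module: the 7-term worked-example DAG and synthetic OBO/GAF data

#' The seven-term cellular-component example DAG
#'
#' The ancestor graph of *intracellular membrane-bounded organelle*
#' (GO:0043231) used throughout the package's worked examples: seven CC
#' terms, six `is_a` edges and two `part_of` edges, rooted at GO:0005575.
#' With semantic contribution factors 0.8 (`is_a`) and 0.6 (`part_of`), the
#' S-value map of GO:0043231 over this graph is
#' \{1.0, 0.8, 0.8, 0.48, 0.288, 0.64, 0.512\}.
#'
#' @return A [go_dag()] with 7 terms and 8 edges.
#' @examples
#' dag <- organelle_dag()
#' ancestors(dag, "GO:0043227")
#' @export
organelle_dag <- function() {
  terms <- c("GO:0005575", "GO:0005622", "GO:0005623", "GO:0043226",
             "GO:0043227", "GO:0043229", "GO:0043231")
  nm <- c("cellular_component", "intracellular", "cell", "organelle",
          "membrane-bounded organelle", "intracellular organelle",
          "intracellular membrane-bounded organelle")
  edges <- data.frame(
    child    = c("GO:0043231", "GO:0043231", "GO:0043229", "GO:0043229",
                 "GO:0043227", "GO:0043226", "GO:0005622", "GO:0005623"),
    parent   = c("GO:0043229", "GO:0043227", "GO:0043226", "GO:0005622",
                 "GO:0043226", "GO:0005575", "GO:0005623", "GO:0005575"),
    relation = c("is_a", "is_a", "is_a", "part_of",
                 "is_a", "is_a", "part_of", "is_a"),
    stringsAsFactors = FALSE)
  go_dag(terms = terms, name = nm, namespace = rep("CC", 7L), edges = edges)
}

#' Generate a random single-root ontology DAG
#'
#' Term `i`'s parents are sampled uniformly from terms `1..i-1`, which
#' guarantees acyclicity and a single root (term 1); each edge is labelled
#' `part_of` with probability `part_of_fraction`, otherwise `is_a`. The
#' output is a deterministic function of the arguments including `seed`.
#' These graphs are structurally valid ontologies but make no attempt at GO
#' realism; they exist to exercise the parsers and certify the fast path
#' against the naive oracles.
#'
#' @param n_terms number of terms (>= 1).
#' @param max_parents maximum parents per non-root term (>= 1).
#' @param part_of_fraction probability an edge is `part_of`, in \[0, 1\].
#' @param seed RNG seed.
#' @param namespace namespace code for all terms (default `"BP"`).
#' @return A [go_dag()].
#' @export
random_dag <- function(n_terms, max_parents = 3L, part_of_fraction = 0.2,
                       seed = 1L, namespace = "BP") {
  if (n_terms < 1L) stop("n_terms must be >= 1", call. = FALSE)
  if (max_parents < 1L) stop("max_parents must be >= 1", call. = FALSE)
  if (part_of_fraction < 0 || part_of_fraction > 1) {
    stop("part_of_fraction must lie in [0, 1]", call. = FALSE)
  }
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  with_seed(seed, {
    e_child <- character(); e_parent <- character(); e_rel <- character()
    for (i in seq_len(n_terms)[-1]) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      pa <- if (i == 2L) 1L else sample.int(i - 1L, k)
      rel <- ifelse(stats::runif(length(pa)) < part_of_fraction, "part_of", "is_a")
      e_child <- c(e_child, rep(ids[i], length(pa)))
      e_parent <- c(e_parent, ids[pa])
      e_rel <- c(e_rel, rel)
    }
    go_dag(terms = ids,
           name = paste("synthetic term", seq_len(n_terms)),
           namespace = rep(normalize_namespace(namespace), n_terms),
           edges = data.frame(child = e_child, parent = e_parent,
                              relation = e_rel, stringsAsFactors = FALSE))
  })
}

#' Generate random gene annotations over a DAG
#'
#' Each gene receives `max(1, Poisson(mean_direct_terms))` direct terms
#' sampled uniformly without replacement from the DAG; evidence code is IEA.
#' Deterministic under `seed`.
#'
#' @param dag a [go_dag()] with a single namespace.
#' @param n_genes number of genes (>= 1).
#' @param mean_direct_terms Poisson mean of direct annotations per gene.
#' @param seed RNG seed.
#' @return An [annotation_set()].
#' @export
random_annotations <- function(dag, n_genes, mean_direct_terms = 2, seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  if (length(dag$roots) != 1L) {
    stop("random_annotations needs a single-namespace dag", call. = FALSE)
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    rec <- lapply(seq_len(n_genes), function(i) {
      k <- max(1L, stats::rpois(1L, mean_direct_terms))
      k <- min(k, length(dag$terms))
      data.frame(gene = genes[i],
                 term = sample(dag$terms, k),
                 evidence = "IEA",
                 symbol = genes[i],
                 stringsAsFactors = FALSE)
    })
    annotation_set(do.call(rbind, rec), namespace = names(dag$roots))
  })
}
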