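# naive reference implementations: every query re-traverses the raw graph
# with no caching. Deliberately slow; they define correctness for the
# table-backed fast path and are compared against it to 1e-12 in the tests.

naive_ancestors <- function(dag, term, relations = NULL) {
  seen <- character()
  visit <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    pa <- dag$parents_of[[t]]
    up <- if (is.null(relations)) names(pa) else names(pa)[pa %in% relations]
    for (p in up) visit(p)
  }
  visit(resolve_term(dag, term))
  sort(seen)
}

# longest path from the root: exhaustive recursion over parent edges
naive_depth <- function(dag, term) {
  pa <- names(dag$parents_of[[term]])
  if (!length(pa)) return(0)
  1 + max(vapply(pa, function(p) naive_depth(dag, p), numeric(1)))
}

# longest path from ancestor `a` down to `x` inside x's ancestor sub-DAG
naive_dist <- function(dag, x, a) {
  if (x == a) return(0)
  pa <- names(dag$parents_of[[x]])
  pa <- pa[vapply(pa, function(p) a %in% naive_ancestors(dag, p), logical(1))]
  1 + max(vapply(pa, function(p) naive_dist(dag, p, a), numeric(1)))
}

# direct annotation count of one term: scan the raw records
naive_direct_count <- function(dag, annset, term) {
  r <- annset$records
  length(unique(r$gene[r$term == term]))
}

# closure counts for every term by the brute-force double loop over
# (term, descendant) pairs; recomputed from the raw graph on every call
naive_closure_counts <- function(dag, annset, mode = "literal") {
  out <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  if (mode == "literal") {
    for (d in dag$terms) {
      n_d <- naive_direct_count(dag, annset, d)
      if (n_d > 0) {
        for (a in naive_ancestors(dag, d)) out[a] <- out[a] + n_d
      }
    }
  } else {
    for (g in names(annset$direct)) {
      cl <- unique(unlist(lapply(annset$direct[[g]], naive_ancestors,
                                 dag = dag), use.names = FALSE))
      out[cl] <- out[cl] + 1
    }
  }
  out
}

naive_closure_count <- function(dag, annset, term, mode = "literal") {
  naive_closure_counts(dag, annset, mode)[[term]]
}

# IC of one or more terms; one fresh closure-count pass per call
naive_ic <- function(dag, annset, term, mode = "literal") {
  counts <- naive_closure_counts(dag, annset, mode)
  total <- counts[[dag$roots[[1]]]]
  cnt <- counts[term]
  if (any(cnt <= 0)) {
    stop("no information content for term(s) ",
         paste(term[cnt <= 0], collapse = ", "), call. = FALSE)
  }
  unname(-log(cnt / total))
}

# Eq.-style recursion for the S-value of ancestor t relative to A,
# memoisation deliberately disabled
naive_svalue <- function(dag, A, t, factors) {
  if (t == A) return(1)
  sub <- naive_ancestors(dag, A, relations = names(factors))
  ch <- dag$children_of[[t]]
  keep <- names(ch)[names(ch) %in% sub & ch %in% names(factors)]
  max(vapply(keep, function(c_) {
    unname(factors[[ch[[c_]]]]) * naive_svalue(dag, A, c_, factors)
  }, numeric(1)))
}

naive_sv <- function(dag, A, factors) {
  sub <- naive_ancestors(dag, A, relations = names(factors))
  sum(vapply(sub, function(t) naive_svalue(dag, A, t, factors), numeric(1)))
}

naive_mica_ic <- function(dag, annset, t1, t2, mode = "literal") {
  common <- intersect(naive_ancestors(dag, t1), naive_ancestors(dag, t2))
  max(naive_ic(dag, annset, common, mode))
}

#' Naive (repeated-traversal) term similarity oracle
#'
#' Recomputes ancestors, information content, depths and S-values from the
#' raw graph and annotation records on every call, with no caching. Slow by
#' design: it is the independent reference that the table-backed fast path
#' must reproduce exactly.
#'
#' @param t1,t2 term IDs.
#' @param dag the raw [go_dag()].
#' @param annset the raw [annotation_set()] (ignored by `pekar`/`wang`).
#' @param measure one of the five pairwise measures.
#' @param factors [semantic_factors()] for `wang`.
#' @param counting closure-count mode for IC-based measures.
#' @param jiang_clamp,pekar_variant variant flags matching [term_sim()].
#' @return Numeric scalar.
#' @export
naive_term_sim <- function(t1, t2, dag, annset,
                           measure = PAIRWISE_MEASURES,
                           factors = semantic_factors(),
                           counting = "literal",
                           jiang_clamp = FALSE,
                           pekar_variant = c("as_printed", "classic")) {
  measure <- match.arg(measure)
  pekar_variant <- match.arg(pekar_variant)
  t1 <- resolve_term(dag, t1); t2 <- resolve_term(dag, t2)
  if (measure == "resnik") {
    return(naive_mica_ic(dag, annset, t1, t2, counting))
  }
  if (measure == "lin") {
    if (t1 == t2) return(1)
    denom <- naive_ic(dag, annset, t1, counting) +
      naive_ic(dag, annset, t2, counting)
    if (denom == 0) return(0)
    return(2 * naive_mica_ic(dag, annset, t1, t2, counting) / denom)
  }
  if (measure == "jiang") {
    if (t1 == t2) return(1)
    out <- 1 - (naive_ic(dag, annset, t1, counting) +
                  naive_ic(dag, annset, t2, counting) -
                  2 * naive_mica_ic(dag, annset, t1, t2, counting))
    return(if (jiang_clamp) max(out, 0) else out)
  }
  if (measure == "pekar") {
    common <- intersect(naive_ancestors(dag, t1), naive_ancestors(dag, t2))
    d <- vapply(common, function(t) naive_depth(dag, t), numeric(1))
    ta <- sort(common[d == max(d)])[1L]
    da <- naive_depth(dag, ta)
    denom <- if (pekar_variant == "as_printed") {
      da + naive_depth(dag, t1) + naive_depth(dag, t2)
    } else {
      naive_dist(dag, t1, ta) + naive_dist(dag, t2, ta) + da
    }
    if (denom == 0) return(0)
    return(da / denom)
  }
  # wang
  if (t1 == t2) return(1)
  sub1 <- naive_ancestors(dag, t1, relations = names(factors))
  sub2 <- naive_ancestors(dag, t2, relations = names(factors))
  shared <- intersect(sub1, sub2)
  num <- sum(vapply(shared, function(t) {
    naive_svalue(dag, t1, t, factors) + naive_svalue(dag, t2, t, factors)
  }, numeric(1)))
  num / (naive_sv(dag, t1, factors) + naive_sv(dag, t2, factors))
}

#' Naive (repeated-traversal) gene similarity oracle
#'
#' Pairwise measures: recomputes every term-term similarity with
#' [naive_term_sim()] over the genes' direct annotation sets and applies
#' the combination rule by direct formula evaluation. Group-wise measures:
#' recomputes annotation closures by fresh graph traversal.
#'
#' @param g1,g2 gene IDs in `annset`.
#' @inheritParams naive_term_sim
#' @param measure any of the seven measures.
#' @param rule combination rule for pairwise measures.
#' @return Numeric scalar.
#' @export
naive_gene_sim <- function(g1, g2, dag, annset,
                           measure = c(PAIRWISE_MEASURES, GROUPWISE_MEASURES),
                           rule = c("bma", "max", "avg"),
                           factors = semantic_factors(),
                           counting = "literal",
                           jiang_clamp = FALSE,
                           pekar_variant = c("as_printed", "classic")) {
  measure <- match.arg(measure)
  for (g in c(g1, g2)) {
    if (is.null(annset$direct[[g]]) || !length(annset$direct[[g]])) {
      stop("gene ", g, " has no annotation", call. = FALSE)
    }
  }
  if (measure %in% GROUPWISE_MEASURES) {
    closure_of <- function(g) {
      sort(unique(unlist(lapply(annset$direct[[g]], naive_ancestors, dag = dag),
                         use.names = FALSE)))
    }
    a <- closure_of(g1); b <- closure_of(g2)
    if (measure == "simui") {
      return(length(intersect(a, b)) / length(union(a, b)))
    }
    u <- union(a, b)
    ic_u <- naive_ic(dag, annset, u, counting)
    denom <- sum(ic_u)
    if (denom == 0) return(if (setequal(a, b)) 1 else 0)
    return(sum(ic_u[u %in% intersect(a, b)]) / denom)
  }
  rule <- match.arg(rule)
  ts1 <- annset$direct[[g1]]; ts2 <- annset$direct[[g2]]
  m <- matrix(0, length(ts1), length(ts2))
  for (i in seq_along(ts1)) {
    for (j in seq_along(ts2)) {
      m[i, j] <- naive_term_sim(ts1[i], ts2[j], dag, annset, measure,
                                factors = factors, counting = counting,
                                jiang_clamp = jiang_clamp,
                                pekar_variant = pekar_variant)
    }
  }
  if (rule == "max") return(max(m))
  if (rule == "avg") return(sum(m) / (nrow(m) * ncol(m)))
  row_best <- vapply(seq_len(nrow(m)), function(i) max(m[i, ]), numeric(1))
  col_best <- vapply(seq_len(ncol(m)), function(j) max(m[, j]), numeric(1))
  (sum(row_best) + sum(col_best)) / (nrow(m) + ncol(m))
}
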