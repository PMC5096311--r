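# pairwise similarity: term-term measures answered from the lookup tables
# only, plus the max / average / best-match-average gene-level rules.

PAIRWISE_MEASURES <- c("resnik", "lin", "jiang", "pekar", "wang")
GROUPWISE_MEASURES <- c("simui", "simgic")

check_term_in_tables <- function(tables, term) {
  term <- normalize_term_id(term)
  if (is.null(tables$anc[[term]])) {
    stop("unknown term: ", term, " (not in the ", tables$namespace,
         " table set)", call. = FALSE)
  }
  term
}

ic_of <- function(tables, terms) {
  ic <- tables$ic[terms]
  if (anyNA(ic)) {
    stop("no information content for term(s) ",
         paste(terms[is.na(ic)], collapse = ", "),
         " (zero annotations in the corpus)", call. = FALSE)
  }
  ic
}

#' Most informative common ancestor
#'
#' Intersects the stored ancestor sets of the two terms and returns the
#' common ancestor with maximal information content; ties are broken by the
#' lexicographically smallest term ID.
#'
#' @param t1,t2 term IDs (same namespace).
#' @param tables a [build_tables()] / [load_tables()] result.
#' @return List with elements `term` and `ic`.
#' @export
mica <- function(t1, t2, tables) {
  t1 <- check_term_in_tables(tables, t1)
  t2 <- check_term_in_tables(tables, t2)
  if (t1 == t2) {
    return(list(term = t1, ic = unname(ic_of(tables, t1))))
  }
  common <- intersect(tables$anc[[t1]], tables$anc[[t2]])
  stopifnot(length(common) > 0L)  # the namespace root is always shared
  ic <- ic_of(tables, common)
  best <- common[ic == max(ic)]
  pick <- sort(best)[1L]
  list(term = pick, ic = unname(ic[[pick]]))
}

#' Resnik term similarity
#'
#' The information content of the most informative common ancestor.
#' Non-negative; zero when the only common ancestor is the root.
#' @inheritParams mica
#' @return Numeric scalar.
#' @export
sim_resnik <- function(t1, t2, tables) {
  mica(t1, t2, tables)$ic
}

#' Lin term similarity
#'
#' `2 * IC(MICA) / (IC(t1) + IC(t2))`, in \[0, 1\]. Identical terms score 1
#' even when their IC is 0; distinct terms with zero IC sum score 0.
#' @inheritParams mica
#' @return Numeric scalar in \[0, 1\].
#' @export
sim_lin <- function(t1, t2, tables) {
  t1 <- check_term_in_tables(tables, t1)
  t2 <- check_term_in_tables(tables, t2)
  if (t1 == t2) {
    ic_of(tables, t1)  # presence check only
    return(1)
  }
  ic12 <- ic_of(tables, c(t1, t2))
  denom <- sum(ic12)
  if (denom == 0) return(0)
  2 * mica(t1, t2, tables)$ic / denom
}

#' Jiang-Conrath term similarity
#'
#' `1 - (IC(t1) + IC(t2) - 2 * IC(MICA))`: one minus the Jiang-Conrath
#' semantic distance. Unbounded below (can be negative) unless `clamp` is
#' set, in which case negative values are raised to 0. Always 1 for
#' identical terms.
#' @inheritParams mica
#' @param clamp clamp negative values to 0 (default `FALSE`).
#' @return Numeric scalar, at most 1.
#' @export
sim_jiang <- function(t1, t2, tables, clamp = FALSE) {
  t1 <- check_term_in_tables(tables, t1)
  t2 <- check_term_in_tables(tables, t2)
  ic12 <- ic_of(tables, unique(c(t1, t2)))
  if (t1 == t2) return(1)
  out <- 1 - (sum(ic12) - 2 * mica(t1, t2, tables)$ic)
  if (clamp) max(out, 0) else out
}

# deepest common ancestor; ties by smallest ID
deepest_common_ancestor <- function(t1, t2, tables) {
  common <- intersect(tables$anc[[t1]], tables$anc[[t2]])
  d <- tables$depth[common]
  sort(common[d == max(d)])[1L]
}

#' Pekar-Staab term similarity
#'
#' Both variants pick the common ancestor `t_a` of maximal longest-path
#' depth. The `"as_printed"` variant scores
#' `depth(t_a) / (depth(t_a) + depth(t1) + depth(t2))` using root depths
#' only. The `"classic"` variant scores
#' `depth(t_a) / (d(t1, t_a) + d(t2, t_a) + depth(t_a))`, where `d(x, t_a)`
#' is the longest path from `t_a` down to `x` inside the ancestor sub-DAG of
#' `x`; under it, every non-root term has self-similarity 1. A degenerate
#' 0/0 (all depths zero) scores 0.
#' @inheritParams mica
#' @param variant `"as_printed"` (default) or `"classic"`.
#' @return Numeric scalar in \[0, 1\].
#' @export
sim_pekar <- function(t1, t2, tables, variant = c("as_printed", "classic")) {
  variant <- match.arg(variant)
  t1 <- check_term_in_tables(tables, t1)
  t2 <- check_term_in_tables(tables, t2)
  ta <- deepest_common_ancestor(t1, t2, tables)
  da <- tables$depth[[ta]]
  if (variant == "as_printed") {
    denom <- da + tables$depth[[t1]] + tables$depth[[t2]]
  } else {
    denom <- tables$dist[[t1]][[ta]] + tables$dist[[t2]][[ta]] + da
  }
  if (denom == 0) return(0)
  da / denom
}

#' Wang term similarity
#'
#' `sum over shared ancestors of (S_A(t) + S_B(t)) / (SV(A) + SV(B))`,
#' evaluated on the stored S-value maps. Identical terms score exactly 1.
#' @inheritParams mica
#' @return Numeric scalar in \[0, 1\].
#' @export
sim_wang <- function(t1, t2, tables) {
  t1 <- normalize_term_id(t1); t2 <- normalize_term_id(t2)
  s1 <- tables$svalues[[t1]]
  if (is.null(s1)) stop("no S-value record for term ", t1, call. = FALSE)
  s2 <- tables$svalues[[t2]]
  if (is.null(s2)) stop("no S-value record for term ", t2, call. = FALSE)
  if (t1 == t2) return(1)
  shared <- intersect(names(s1), names(s2))
  sum(s1[shared] + s2[shared]) / (tables$sv[[t1]] + tables$sv[[t2]])
}

#' Term-term similarity dispatcher
#'
#' @inheritParams mica
#' @param measure one of `"resnik"`, `"lin"`, `"jiang"`, `"pekar"`, `"wang"`.
#' @param jiang_clamp clamp negative Jiang-Conrath values to 0.
#' @param pekar_variant passed to [sim_pekar()].
#' @return Numeric scalar.
#' @export
term_sim <- function(t1, t2, tables, measure = PAIRWISE_MEASURES,
                     jiang_clamp = FALSE,
                     pekar_variant = c("as_printed", "classic")) {
  measure <- match.arg(measure)
  switch(measure,
         resnik = sim_resnik(t1, t2, tables),
         lin = sim_lin(t1, t2, tables),
         jiang = sim_jiang(t1, t2, tables, clamp = jiang_clamp),
         pekar = sim_pekar(t1, t2, tables, variant = pekar_variant),
         wang = sim_wang(t1, t2, tables))
}

#' Combine a term-similarity matrix into one gene-level score
#'
#' `max` is the global maximum; `avg` the mean over all entries; `bma`
#' (best-match average) is `(sum of row maxima + sum of column maxima) /
#' (nrow + ncol)` -- symmetric in the two genes by construction.
#'
#' @param m numeric matrix of term-term similarities (rows: gene 1's terms,
#'   columns: gene 2's terms).
#' @param rule `"max"`, `"avg"` or `"bma"`.
#' @return Numeric scalar.
#' @export
combine_scores <- function(m, rule = c("max", "avg", "bma")) {
  rule <- match.arg(rule)
  m <- as.matrix(m)
  if (!length(m)) stop("empty similarity matrix", call. = FALSE)
  switch(rule,
         max = max(m),
         avg = mean(m),
         bma = (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) /
           (nrow(m) + ncol(m)))
}

gene_direct_terms <- function(tables, gene, annset = NULL) {
  direct <- if (is.null(annset)) tables$gene_direct[[gene]]
            else annset$direct[[gene]]
  if (is.null(direct) || !length(direct)) {
    stop("gene ", gene, " has no annotation in namespace ",
         tables$namespace, call. = FALSE)
  }
  direct
}

#' Gene-gene functional similarity
#'
#' For the pairwise measures, builds the term-similarity matrix over the two
#' genes' *direct* annotation term sets and applies the combination rule.
#' For `"simui"` / `"simgic"` dispatches to the group-wise measures over
#' annotation closures (the rule is ignored).
#'
#' @param g1,g2 gene IDs present in the tables (or in `annset`).
#' @param tables a [build_tables()] / [load_tables()] result.
#' @param measure one of the five pairwise measures or `"simui"`/`"simgic"`.
#' @param rule combination rule for pairwise measures (default `"bma"`).
#' @param jiang_clamp,pekar_variant measure variant flags.
#' @param annset optional [annotation_set()] overriding the stored direct
#'   annotation table.
#' @return Numeric scalar.
#' @export
gene_sim <- function(g1, g2, tables,
                     measure = c(PAIRWISE_MEASURES, GROUPWISE_MEASURES),
                     rule = c("bma", "max", "avg"),
                     jiang_clamp = FALSE,
                     pekar_variant = c("as_printed", "classic"),
                     annset = NULL) {
  measure <- match.arg(measure)
  if (measure %in% GROUPWISE_MEASURES) {
    return(switch(measure,
                  simui = sim_ui(g1, g2, tables),
                  simgic = sim_gic(g1, g2, tables)))
  }
  rule <- match.arg(rule)
  ts1 <- gene_direct_terms(tables, g1, annset)
  ts2 <- gene_direct_terms(tables, g2, annset)
  m <- matrix(0, length(ts1), length(ts2), dimnames = list(ts1, ts2))
  for (i in seq_along(ts1)) {
    for (j in seq_along(ts2)) {
      m[i, j] <- term_sim(ts1[i], ts2[j], tables, measure,
                          jiang_clamp = jiang_clamp,
                          pekar_variant = pekar_variant)
    }
  }
  combine_scores(m, rule)
}
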