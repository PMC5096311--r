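# group-wise similarity: simUI and simGIC over gene annotation closures

gene_set_terms <- function(tables, gene, mode) {
  s <- if (mode == "closure") tables$gene_closure[[gene]]
       else tables$gene_direct[[gene]]
  if (is.null(s) || !length(s)) {
    stop("gene ", gene, " has no annotation in namespace ",
         tables$namespace, call. = FALSE)
  }
  s
}

#' simUI gene similarity
#'
#' The Jaccard ratio of the two genes' annotation term sets:
#' `|A(g1) n A(g2)| / |A(g1) u A(g2)|`. By default `A(g)` is the ancestor
#' closure of the gene's direct terms, so the score is strictly positive
#' within one namespace (the root is always shared).
#'
#' @param g1,g2 gene IDs present in the tables.
#' @param tables a [build_tables()] / [load_tables()] result.
#' @param mode `"closure"` (default) or `"direct"`.
#' @return Numeric scalar in (0, 1\] for closures, \[0, 1\] for direct sets.
#' @export
sim_ui <- function(g1, g2, tables, mode = c("closure", "direct")) {
  mode <- match.arg(mode)
  a <- gene_set_terms(tables, g1, mode)
  b <- gene_set_terms(tables, g2, mode)
  length(intersect(a, b)) / length(union(a, b))
}

#' simGIC gene similarity
#'
#' The IC-weighted Jaccard ratio:
#' `sum IC over A(g1) n A(g2) / sum IC over A(g1) u A(g2)`. When the
#' union's IC sum is zero (all terms are the root), identical sets score 1
#' and different sets 0. Terms without an IC entry (zero annotations in the
#' corpus) raise an error unless `missing_ic = "zero"` treats their IC as 0.
#'
#' @inheritParams sim_ui
#' @param missing_ic `"error"` (default) or `"zero"`.
#' @return Numeric scalar in \[0, 1\].
#' @export
sim_gic <- function(g1, g2, tables, mode = c("closure", "direct"),
                    missing_ic = c("error", "zero")) {
  mode <- match.arg(mode)
  missing_ic <- match.arg(missing_ic)
  a <- gene_set_terms(tables, g1, mode)
  b <- gene_set_terms(tables, g2, mode)
  u <- union(a, b)
  ic_u <- tables$ic[u]
  if (anyNA(ic_u)) {
    if (missing_ic == "error") {
      stop("no information content for term(s) ",
           paste(u[is.na(ic_u)], collapse = ", "),
           " in the closure of ", g1, " / ", g2, call. = FALSE)
    }
    ic_u[is.na(ic_u)] <- 0
  }
  names(ic_u) <- u
  denom <- sum(ic_u)
  if (denom == 0) return(if (setequal(a, b)) 1 else 0)
  sum(ic_u[intersect(a, b)]) / denom
}
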