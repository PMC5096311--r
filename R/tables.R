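# table builder: compile the ontology + corpus into per-method lookup tables.
# After the build, every similarity query is answered from these tables alone;
# the graph object is never consulted again.

#' Semantic contribution factors for Wang S-value propagation
#'
#' One weight per relation type, each strictly between 0 and 1 so that
#' S-values decay along every edge. Relations without a factor never
#' participate in S-value propagation.
#'
#' @param is_a weight for `is_a` edges (default 0.8).
#' @param part_of weight for `part_of` edges (default 0.6).
#' @param ... further `relation = weight` pairs.
#' @return Named numeric vector of class `semantic_factors`.
#' @export
semantic_factors <- function(is_a = 0.8, part_of = 0.6, ...) {
  w <- c(is_a = is_a, part_of = part_of, ...)
  w <- vapply(w, as.numeric, numeric(1))
  if (any(w <= 0 | w >= 1)) {
    stop("semantic contribution factors must lie strictly in (0, 1)",
         call. = FALSE)
  }
  structure(w[order(names(w))], class = "semantic_factors")
}

#' Ancestor lookup table
#'
#' @param dag a [go_dag()].
#' @return Named list: term ID -> sorted character vector of ancestors
#'   including the term itself.
#' @export
build_ancestor_table <- function(dag) {
  topo <- topological_order(dag)
  anc <- vector("list", length(topo))
  names(anc) <- topo
  for (t in topo) {
    up <- names(dag$parents_of[[t]])
    anc[[t]] <- sort(unique(c(t, unlist(anc[up], use.names = FALSE))))
  }
  anc[dag$terms]
}

#' Information-content table
#'
#' `p(t)` is the term's closure count divided by the root's closure count
#' (so `p(root) = 1` exactly) and `ic = -ln p`. Terms with zero closure
#' count are absent from the table; IC-based queries touching them raise an
#' error rather than returning a sentinel.
#'
#' @param dag a single-namespace [go_dag()].
#' @param counts a [term_counts()] built on the same DAG.
#' @return List with named numeric vectors `p` and `ic` (annotated terms
#'   only) and the counting `mode`.
#' @export
build_ic_table <- function(dag, counts) {
  if (length(dag$roots) != 1L) {
    stop("IC table requires a single-namespace dag", call. = FALSE)
  }
  total <- counts$closure[[dag$roots]]
  if (total <= 0) {
    stop("no annotations in namespace ", names(dag$roots), call. = FALSE)
  }
  keep <- counts$closure > 0
  p <- counts$closure[keep] / total
  ic <- -log(p)
  ord <- order(names(p))
  list(p = p[ord], ic = ic[ord], mode = counts$mode)
}

#' Depth and ancestor-distance tables
#'
#' `depth(t)` is the longest-path edge count from the namespace root down to
#' `t`, computed in one topological pass. `dist[[t]]` maps every ancestor
#' `a` of `t` to the longest path length from `a` down to `t` inside the
#' ancestor sub-DAG of `t` (used by the classic Pekar-Staab variant);
#' `dist[[t]][root]` equals `depth(t)`.
#'
#' @param dag a [go_dag()].
#' @return List with named numeric vector `depth` and named list `dist`.
#' @export
build_depth_table <- function(dag) {
  topo <- topological_order(dag)
  dist <- vector("list", length(topo))
  names(dist) <- topo
  depth <- stats::setNames(numeric(length(topo)), topo)
  for (t in topo) {
    d <- stats::setNames(0, t)
    for (p in names(dag$parents_of[[t]])) {
      cand <- dist[[p]] + 1
      merged <- union(names(d), names(cand))
      d <- stats::setNames(
        pmax(d[merged], cand[merged], na.rm = TRUE), merged)
    }
    d <- d[order(names(d))]
    dist[[t]] <- d
    depth[[t]] <- max(d)
  }
  list(depth = depth[dag$terms], dist = dist[dag$terms])
}

# ancestors reachable through edges whose relation carries a factor
restricted_ancestors <- function(dag, term, relations) {
  ancestors(dag, term, relations = relations)
}

#' Wang S-value table
#'
#' For every term `A`, computes the S-value of each ancestor `t` in the
#' ancestor sub-DAG of `A`: `S_A(A) = 1`, and otherwise the maximum over
#' children `t'` of `t` inside the sub-DAG of `w_e * S_A(t')`, where `w_e`
#' is the semantic contribution factor of the edge. `sv[A]` is the semantic
#' value `SV(A)`, the sum of all S-values of `A`. Only edges whose relation
#' has a configured factor propagate (and define sub-DAG reachability here).
#'
#' @param dag a [go_dag()].
#' @param factors a [semantic_factors()] vector.
#' @return List with named list `svalues` (term -> named numeric map over
#'   its ancestors) and named numeric vector `sv`.
#' @export
build_svalue_table <- function(dag, factors = semantic_factors()) {
  topo <- topological_order(dag)
  pos <- stats::setNames(seq_along(topo), topo)
  rels <- names(factors)
  svalues <- vector("list", length(dag$terms))
  names(svalues) <- dag$terms
  sv <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  for (A in dag$terms) {
    sub <- restricted_ancestors(dag, A, rels)
    # children before parents: walk the sub-DAG in reverse topological order
    ord <- sub[order(pos[sub], decreasing = TRUE)]
    s <- stats::setNames(numeric(length(ord)), ord)
    s[[A]] <- 1
    for (t in ord[ord != A]) {
      ch <- dag$children_of[[t]]
      keep <- names(ch)[names(ch) %in% sub & ch %in% rels]
      s[[t]] <- max(unname(factors[ch[keep]]) * s[keep])
    }
    s <- s[order(names(s))]
    svalues[[A]] <- s
    sv[[A]] <- sum(s)
  }
  list(svalues = svalues, sv = sv)
}

#' Gene annotation-closure table
#'
#' `closure(g)` is the union of the ancestor sets of the gene's direct
#' terms (true-path rule); it always contains the namespace root. Genes with
#' no direct annotation are dropped with a warning.
#'
#' @param annset an [annotation_set()].
#' @param dag the matching [go_dag()].
#' @param anc optional precomputed [build_ancestor_table()] output.
#' @return Named list: gene -> sorted character vector of closure terms.
#' @export
build_gene_table <- function(annset, dag, anc = NULL) {
  if (names(dag$roots) != annset$namespace) {
    stop("annotation namespace does not match the dag", call. = FALSE)
  }
  if (is.null(anc)) anc <- build_ancestor_table(dag)
  empty <- names(annset$direct)[lengths(annset$direct) == 0L]
  if (length(empty)) {
    warning("dropping gene(s) with no direct annotation: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  genes <- setdiff(names(annset$direct), empty)
  out <- lapply(annset$direct[genes], function(ts) {
    sort(unique(unlist(anc[ts], use.names = FALSE)))
  })
  out[order(names(out))]
}

#' Build the full lookup-table set for one namespace
#'
#' One-shot compilation of the ontology and corpus into every per-method
#' lookup table: ancestor sets, information content, longest-path depths
#' (with per-term ancestor distances), Wang S-value maps, and per-gene
#' direct and closure term sets. Queries made against the result never touch
#' the `go_dag` again.
#'
#' @param dag a single-namespace [go_dag()].
#' @param annset an [annotation_set()] on the same namespace.
#' @param factors a [semantic_factors()] vector.
#' @param counting closure-count mode passed to [term_counts()].
#' @return Object of class `go_tables`: list with elements `namespace`,
#'   `factors`, `counting`, `p`, `ic`, `depth`, `dist`, `svalues`, `sv`,
#'   `anc`, `gene_direct`, `gene_closure`, `n_terms`.
#' @examples
#' dag <- organelle_dag()
#' ann <- annotation_set(
#'   data.frame(gene = c("gA", "gB"), term = c("GO:0043227", "GO:0005622")),
#'   namespace = "CC")
#' tab <- build_tables(dag, ann)
#' sim_wang("GO:0043227", "GO:0005622", tab)
#' @export
build_tables <- function(dag, annset, factors = semantic_factors(),
                         counting = c("literal", "distinct")) {
  counting <- match.arg(counting)
  if (length(dag$roots) != 1L) {
    stop("build_tables requires a single-namespace dag; use parse_obo(namespace=)",
         call. = FALSE)
  }
  counts <- term_counts(annset, dag, mode = counting)
  anc <- build_ancestor_table(dag)
  ict <- build_ic_table(dag, counts)
  dep <- build_depth_table(dag)
  svt <- build_svalue_table(dag, factors)
  gene_closure <- build_gene_table(annset, dag, anc = anc)
  gene_direct <- lapply(annset$direct, function(x) sort(unique(x)))
  gene_direct <- gene_direct[order(names(gene_direct))]
  structure(
    list(namespace = names(dag$roots),
         factors = factors,
         counting = counting,
         p = ict$p, ic = ict$ic,
         depth = dep$depth, dist = dep$dist,
         svalues = svt$svalues, sv = svt$sv,
         anc = anc,
         gene_direct = gene_direct,
         gene_closure = gene_closure,
         n_terms = length(dag$terms)),
    class = "go_tables")
}

#' @export
print.go_tables <- function(x, ...) {
  cat("go_tables (namespace ", x$namespace, "): ", x$n_terms, " terms, ",
      length(x$ic), " with IC, ", length(x$gene_closure), " genes\n", sep = "")
  cat("  factors:",
      paste(names(x$factors), unname(x$factors), sep = "=", collapse = ", "),
      "| counting:", x$counting, "\n")
  invisible(x)
}

## ---- serialisation ---------------------------------------------------------
## Plain TSV, one record per line, reals at 17 significant digits so that
## save -> load reproduces every double bit-for-bit. All files are written
## with sorted keys: identical inputs give byte-identical table directories.

write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

read_tsv_cols <- function(path, n_col) {
  if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != n_col)) {
    stop("truncated or malformed table file: ", path, call. = FALSE)
  }
  lapply(seq_len(n_col), function(i) vapply(parts, `[[`, character(1), i))
}

#' Save lookup tables to a directory of TSV files
#'
#' Layout: `ic.tsv` (term, p, ic), `depth.tsv` (term, depth), `dists.tsv`
#' (term, ancestor, dist), `svalues.tsv` (term, ancestor, svalue), `sv.tsv`
#' (term, sv), `ancestors.tsv` (term, ancestor), `genes.tsv` (gene, closure
#' term), `genes_direct.tsv` (gene, direct term) and `manifest.txt`
#' (key=value: namespace, factors, counting mode, log base, row counts).
#' Reals are printed with 17 significant digits, so [load_tables()]
#' reproduces them exactly.
#'
#' @param tables a [build_tables()] result.
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
save_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "go_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_tsv_lines(paste(names(tables$ic), fmt_real(tables$p[names(tables$ic)]),
                        fmt_real(tables$ic), sep = "\t"), p("ic.tsv"))
  write_tsv_lines(paste(names(tables$depth), fmt_real(tables$depth), sep = "\t"),
                  p("depth.tsv"))
  flat_map <- function(maps) {
    unlist(lapply(names(maps), function(k) {
      m <- maps[[k]]
      paste(k, names(m), fmt_real(m), sep = "\t")
    }), use.names = FALSE)
  }
  write_tsv_lines(flat_map(tables$dist), p("dists.tsv"))
  write_tsv_lines(flat_map(tables$svalues), p("svalues.tsv"))
  write_tsv_lines(paste(names(tables$sv), fmt_real(tables$sv), sep = "\t"),
                  p("sv.tsv"))
  flat_set <- function(sets) {
    unlist(lapply(names(sets), function(k) paste(k, sets[[k]], sep = "\t")),
           use.names = FALSE)
  }
  write_tsv_lines(flat_set(tables$anc), p("ancestors.tsv"))
  write_tsv_lines(flat_set(tables$gene_closure), p("genes.tsv"))
  write_tsv_lines(flat_set(tables$gene_direct), p("genes_direct.tsv"))

  manifest <- c(
    paste0("tool=gosimtab"),
    paste0("version=", as.character(utils::packageVersion("gosimtab"))),
    paste0("namespace=", tables$namespace),
    paste0("counting=", tables$counting),
    paste0("log_base=natural"),
    paste0("factor.", names(tables$factors), "=", fmt_real(tables$factors)),
    paste0("n_terms=", tables$n_terms),
    paste0("rows.ic=", length(tables$ic)),
    paste0("rows.depth=", length(tables$depth)),
    paste0("rows.sv=", length(tables$sv)),
    paste0("rows.svalues=", sum(lengths(tables$svalues))),
    paste0("rows.dists=", sum(lengths(tables$dist))),
    paste0("rows.ancestors=", sum(lengths(tables$anc))),
    paste0("rows.genes=", sum(lengths(tables$gene_closure))),
    paste0("rows.genes_direct=", sum(lengths(tables$gene_direct))))
  write_tsv_lines(manifest, p("manifest.txt"))
  invisible(p("manifest.txt"))
}

#' Load lookup tables from a table directory
#'
#' Restores a [save_tables()] directory; every stored real compares equal
#' bit-for-bit with the value that was saved. Row counts are checked against
#' the manifest, and a manifest whose semantic factors differ from a
#' requested `factors` argument is refused.
#'
#' @param dir the table directory.
#' @param factors optional [semantic_factors()]; when given, the load fails
#'   unless the manifest declares exactly these factors.
#' @return A `go_tables` object.
#' @export
load_tables <- function(dir, factors = NULL) {
  mf_path <- file.path(dir, "manifest.txt")
  if (!file.exists(mf_path)) stop("missing manifest: ", mf_path, call. = FALSE)
  kv <- readLines(mf_path, warn = FALSE)
  kv <- kv[nzchar(kv)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  manifest <- stats::setNames(vals, keys)

  f_keys <- grep("^factor\\.", keys, value = TRUE)
  m_factors <- stats::setNames(as.numeric(manifest[f_keys]),
                               sub("^factor\\.", "", f_keys))
  m_factors <- m_factors[order(names(m_factors))]
  if (!is.null(factors)) {
    factors <- factors[order(names(factors))]
    if (!identical(names(m_factors), names(factors)) ||
        !identical(unname(m_factors), as.numeric(unname(factors)))) {
      stop("table directory was built with different semantic factors (",
           paste(names(m_factors), m_factors, sep = "=", collapse = ", "),
           ")", call. = FALSE)
    }
  }

  p <- function(f) file.path(dir, f)
  check_rows <- function(n, key) {
    want <- as.integer(manifest[[key]])
    if (!identical(as.integer(n), want)) {
      stop("table file row count mismatch for ", key, ": expected ", want,
           ", found ", n, " (truncated file?)", call. = FALSE)
    }
  }

  ic_c <- read_tsv_cols(p("ic.tsv"), 3L)
  check_rows(length(ic_c[[1]]), "rows.ic")
  dep_c <- read_tsv_cols(p("depth.tsv"), 2L)
  check_rows(length(dep_c[[1]]), "rows.depth")
  sv_c <- read_tsv_cols(p("sv.tsv"), 2L)
  check_rows(length(sv_c[[1]]), "rows.sv")
  sval_c <- read_tsv_cols(p("svalues.tsv"), 3L)
  check_rows(length(sval_c[[1]]), "rows.svalues")
  dist_c <- read_tsv_cols(p("dists.tsv"), 3L)
  check_rows(length(dist_c[[1]]), "rows.dists")
  anc_c <- read_tsv_cols(p("ancestors.tsv"), 2L)
  check_rows(length(anc_c[[1]]), "rows.ancestors")
  gen_c <- read_tsv_cols(p("genes.tsv"), 2L)
  check_rows(length(gen_c[[1]]), "rows.genes")
  gdir_c <- read_tsv_cols(p("genes_direct.tsv"), 2L)
  check_rows(length(gdir_c[[1]]), "rows.genes_direct")

  nest_map <- function(key, sub, val) {
    lapply(split(stats::setNames(as.numeric(val), sub), key), identity)
  }
  nest_set <- function(key, val) split(val, key)

  svalues <- nest_map(sval_c[[1]], sval_c[[2]], sval_c[[3]])
  dist <- nest_map(dist_c[[1]], dist_c[[2]], dist_c[[3]])

  structure(
    list(namespace = manifest[["namespace"]],
         factors = do.call(semantic_factors, as.list(m_factors)),
         counting = manifest[["counting"]],
         p = stats::setNames(as.numeric(ic_c[[2]]), ic_c[[1]]),
         ic = stats::setNames(as.numeric(ic_c[[3]]), ic_c[[1]]),
         depth = stats::setNames(as.numeric(dep_c[[2]]), dep_c[[1]]),
         dist = dist,
         svalues = svalues,
         sv = stats::setNames(as.numeric(sv_c[[2]]), sv_c[[1]]),
         anc = nest_set(anc_c[[1]], anc_c[[2]]),
         gene_direct = nest_set(gdir_c[[1]], gdir_c[[2]]),
         gene_closure = nest_set(gen_c[[1]], gen_c[[2]]),
         n_terms = as.integer(manifest[["n_terms"]])),
    class = "go_tables")
}
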