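# ontology module: OBO parsing and structural queries on the GO DAG

#' Construct a validated GO DAG object
#'
#' Low-level constructor used by [parse_obo()] and the fixture generators.
#' Edges are directed child -> parent and typed by relation (`is_a`,
#' `part_of`, or any other relationship label found in the ontology).
#'
#' @param terms character vector of term IDs (`GO:` + 7 digits).
#' @param name named character vector of term names (names = term IDs).
#' @param namespace named character vector of namespace codes (`BP`, `MF`,
#'   `CC`), one per term.
#' @param edges data frame with columns `child`, `parent`, `relation`.
#' @param alt_ids named character vector mapping alternative IDs to primary
#'   IDs (may be empty).
#' @param obsolete character vector of obsolete term IDs (never connected).
#' @param report list of parse counts, kept for diagnostics.
#'
#' @return An object of class `go_dag`: a list with elements `terms`, `name`,
#'   `namespace`, `edges`, `parents_of`, `children_of`, `roots`, `alt_ids`,
#'   `obsolete`, `report`. Adjacency lists are named character vectors whose
#'   names are the neighbouring term IDs and whose values are relation labels.
#'
#' @details Validation enforces: unique term IDs; every edge joins two defined
#'   terms of the same namespace; the graph is acyclic; exactly one parentless
#'   (root) term per namespace present; obsolete terms appear in no edge.
#' @export
go_dag <- function(terms, name, namespace, edges,
                   alt_ids = character(), obsolete = character(),
                   report = list()) {
  terms <- normalize_term_id(terms)
  if (anyDuplicated(terms)) {
    stop("duplicate term IDs: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(terms)
  terms <- terms[ord]
  name <- as.character(name)[ord]
  namespace <- normalize_namespace(as.character(namespace)[ord])
  names(name) <- names(namespace) <- terms

  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges$child <- normalize_term_id(edges$child)
    edges$parent <- normalize_term_id(edges$parent)
    edges$relation <- as.character(edges$relation)
    missing <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(missing)) {
      stop("edge endpoint(s) not defined as terms: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    cross <- namespace[edges$child] != namespace[edges$parent]
    if (any(cross)) {
      stop("edge(s) joining terms of different namespaces: ",
           paste(edges$child[cross], "->", edges$parent[cross], collapse = "; "),
           call. = FALSE)
    }
    edges <- unique(edges[order(edges$child, edges$parent, edges$relation),
                          c("child", "parent", "relation")])
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  if (length(obsolete)) {
    obsolete <- sort(unique(normalize_term_id(obsolete)))
    if (any(obsolete %in% c(edges$child, edges$parent))) {
      stop("obsolete term(s) appear in edges", call. = FALSE)
    }
    if (any(obsolete %in% terms)) {
      stop("term(s) listed both live and obsolete: ",
           paste(intersect(obsolete, terms), collapse = ", "), call. = FALSE)
    }
  }
  if (length(alt_ids)) {
    alt_ids <- vapply(alt_ids, normalize_term_id, character(1))
    names(alt_ids) <- normalize_term_id(names(alt_ids))
    bad <- !(alt_ids %in% terms)
    if (any(bad)) {
      stop("alt_id target(s) not defined: ",
           paste(unique(alt_ids[bad]), collapse = ", "), call. = FALSE)
    }
    alt_ids <- alt_ids[order(names(alt_ids))]
  } else {
    alt_ids <- character()
  }

  parents_of <- rep(list(character()), length(terms))
  children_of <- rep(list(character()), length(terms))
  names(parents_of) <- names(children_of) <- terms
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      c_ <- edges$child[i]; p_ <- edges$parent[i]; r_ <- edges$relation[i]
      parents_of[[c_]][p_] <- r_
      children_of[[p_]][c_] <- r_
    }
  }

  dag <- structure(
    list(terms = terms, name = name, namespace = namespace, edges = edges,
         parents_of = parents_of, children_of = children_of,
         roots = character(), alt_ids = alt_ids, obsolete = obsolete,
         report = report),
    class = "go_dag")

  # cycle check doubles as the topological-sort validation
  topo <- kahn_order(dag)
  if (length(topo) < length(terms)) {
    cyc <- find_cycle(dag, setdiff(terms, topo))
    stop("ontology graph contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }

  parentless <- terms[vapply(parents_of, length, integer(1)) == 0L]
  roots <- character()
  for (ns in unique(namespace)) {
    r <- parentless[namespace[parentless] == ns]
    if (length(r) != 1L) {
      stop("namespace ", ns, " must have exactly one root, found ",
           length(r), ": ", paste(r, collapse = ", "), call. = FALSE)
    }
    roots[ns] <- r
  }
  dag$roots <- roots
  dag
}

# Kahn's algorithm with lexicographic tie-break; returns the terms it could
# order (all of them iff acyclic), parents before children.
kahn_order <- function(dag) {
  indeg <- vapply(dag$parents_of, length, integer(1))
  ready <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(ready)) {
    t <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, t)
    for (ch in names(dag$children_of[[t]])) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        ready <- sort(c(ready, ch))
      }
    }
  }
  out
}

# walk parent pointers among the unordered (cyclic) terms until one repeats
find_cycle <- function(dag, residue) {
  cur <- residue[1L]
  path <- character()
  while (!(cur %in% path)) {
    path <- c(path, cur)
    nxt <- intersect(names(dag$parents_of[[cur]]), residue)
    cur <- nxt[1L]
  }
  c(path[which(path == cur):length(path)], cur)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", length(x$terms), "terms,", nrow(x$edges), "edges;",
      "namespaces:", paste(names(x$roots), collapse = ", "), "\n")
  if (length(x$obsolete)) cat("  obsolete terms:", length(x$obsolete), "\n")
  if (length(x$alt_ids)) cat("  alternative IDs:", length(x$alt_ids), "\n")
  invisible(x)
}

# map an ID through alt_ids and check it exists
resolve_term <- function(dag, term) {
  term <- normalize_term_id(term)
  hit <- match(term, names(dag$alt_ids))
  term[!is.na(hit)] <- dag$alt_ids[hit[!is.na(hit)]]
  unknown <- setdiff(term, dag$terms)
  if (length(unknown)) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  term
}

#' Ancestor set of a term (reflexive)
#'
#' Returns the reflexive transitive closure over child -> parent edges:
#' the term itself, its parents, their parents, up to the namespace root.
#'
#' @param dag a [go_dag()] object.
#' @param term a single term ID (alternative IDs are resolved).
#' @param relations optional character vector restricting the walk to edges
#'   whose relation label is listed; `NULL` (default) uses every stored edge.
#' @return Sorted character vector of term IDs, always containing `term`.
#' @export
ancestors <- function(dag, term, relations = NULL) {
  term <- resolve_term(dag, term)
  stopifnot(length(term) == 1L)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    up <- unlist(lapply(frontier, function(t) {
      pa <- dag$parents_of[[t]]
      if (is.null(relations)) names(pa) else names(pa)[pa %in% relations]
    }), use.names = FALSE)
    frontier <- setdiff(unique(up), seen)
  }
  sort(unique(seen))
}

#' Descendant set of a term
#'
#' @inheritParams ancestors
#' @param include_self include `term` itself (default `FALSE`, i.e. strict
#'   descendants, matching the annotation-closure count definition).
#' @return Sorted character vector of term IDs.
#' @export
descendants <- function(dag, term, include_self = FALSE) {
  term <- resolve_term(dag, term)
  stopifnot(length(term) == 1L)
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    down <- unlist(lapply(frontier, function(t) names(dag$children_of[[t]])),
                   use.names = FALSE)
    frontier <- setdiff(unique(down), seen)
  }
  out <- sort(unique(seen))
  if (!include_self) out <- setdiff(out, term)
  out
}

#' Deterministic topological order of the DAG
#'
#' Every term appears after all of its parents; ties are broken by
#' lexicographic term ID, so the order is a pure function of the graph.
#'
#' @param dag a [go_dag()] object.
#' @return Character vector of all term IDs.
#' @export
topological_order <- function(dag) {
  kahn_order(dag)
}

#' Parse an OBO 1.2/1.4 flat file into a GO DAG
#'
#' Reads `[Term]` stanzas (fields `id`, `name`, `namespace`, `is_a`,
#' `relationship`, `alt_id`, `is_obsolete`). Obsolete terms are collected but
#' excluded from the graph; alternative IDs are resolved to primary IDs at
#' parse time; relationship types other than `is_a`/`part_of` are retained
#' with their own relation label. Edges joining terms of different namespaces
#' are dropped and counted in the parse report, as are edges pointing at
#' obsolete terms.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @param namespace optional namespace filter (`"BP"`, `"MF"` or `"CC"`);
#'   terms of other namespaces are dropped before graph construction.
#' @return A [go_dag()] whose `report` element counts terms, edges, obsolete
#'   stanzas and dropped edges.
#' @examples
#' dag <- organelle_dag()
#' dag2 <- parse_obo(emit_obo(dag))
#' identical(dag$edges, dag2$edges)
#' @export
parse_obo <- function(x, namespace = NULL) {
  lines <- read_text_input(x)
  lines <- sub("\r$", "", lines)

  stanzas <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() if (!is.null(cur) && !is.null(cur$id)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      cur <- list(is_a = character(), relationship = character(),
                  alt_id = character())
      in_term <- identical(ln, "[Term]")
      next
    }
    if (!in_term || !nzchar(trimws(ln)) || startsWith(ln, "!")) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) < 3L) next
    key <- m[2]; val <- trimws(sub("\\s!\\s.*$", "", m[3]))
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "relationship") cur$relationship <- c(cur$relationship, val)
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete") cur$obsolete <- tolower(val) %in% c("true", "1")
  }
  flush()
  if (!length(stanzas)) stop("no [Term] stanzas found", call. = FALSE)

  obsolete <- character()
  ids <- character(); nm <- character(); ns <- character()
  alt_from <- character(); alt_to <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()
  for (s in stanzas) {
    id <- normalize_term_id(s$id)
    if (isTRUE(s$obsolete)) {
      obsolete <- c(obsolete, id)
      next
    }
    if (is.null(s$namespace)) {
      stop("term ", id, " has no namespace", call. = FALSE)
    }
    ids <- c(ids, id)
    nm <- c(nm, s$name %||% "")
    ns <- c(ns, normalize_namespace(s$namespace))
    if (length(s$alt_id)) {
      alt_from <- c(alt_from, normalize_term_id(s$alt_id))
      alt_to <- c(alt_to, rep(id, length(s$alt_id)))
    }
    for (p in s$is_a) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, normalize_term_id(p))
      e_rel <- c(e_rel, "is_a")
    }
    for (r in s$relationship) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed relationship line in term ", id, ": ", r, call. = FALSE)
      }
      e_child <- c(e_child, id); e_parent <- c(e_parent, normalize_term_id(parts[2]))
      e_rel <- c(e_rel, parts[1])
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term stanzas: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  ns_named <- stats::setNames(ns, ids)
  alt_map <- stats::setNames(alt_to, alt_from)

  # resolve parents through alt ids, then classify
  if (length(e_parent)) {
    hit <- match(e_parent, names(alt_map))
    e_parent[!is.na(hit)] <- unname(alt_map[hit[!is.na(hit)]])
  }
  dropped_obsolete_parent <- 0L
  if (length(e_parent)) {
    keep <- !(e_parent %in% obsolete) & !(e_child %in% obsolete)
    dropped_obsolete_parent <- sum(!keep)
    e_child <- e_child[keep]; e_parent <- e_parent[keep]; e_rel <- e_rel[keep]
  }
  undefined <- setdiff(e_parent, ids)
  if (length(undefined)) {
    stop("term(s) referenced as parent but never defined: ",
         paste(undefined, collapse = ", "), call. = FALSE)
  }
  dropped_cross_ns <- 0L
  if (length(e_parent)) {
    keep <- ns_named[e_child] == ns_named[e_parent]
    dropped_cross_ns <- sum(!keep)
    e_child <- e_child[keep]; e_parent <- e_parent[keep]; e_rel <- e_rel[keep]
  }

  dropped_other_ns <- 0L
  if (!is.null(namespace)) {
    namespace <- normalize_namespace(namespace)
    keep_t <- ns_named[ids] == namespace
    dropped_other_ns <- sum(!keep_t)
    drop_ids <- ids[!keep_t]
    ids <- ids[keep_t]; nm <- nm[keep_t]; ns <- ns[keep_t]
    if (length(e_parent)) {
      keep_e <- !(e_child %in% drop_ids) & !(e_parent %in% drop_ids)
      e_child <- e_child[keep_e]; e_parent <- e_parent[keep_e]; e_rel <- e_rel[keep_e]
    }
    alt_map <- alt_map[alt_map %in% ids]
    if (!length(ids)) stop("no terms left after namespace filter", call. = FALSE)
  }

  report <- list(terms = length(ids),
                 edges = length(e_child),
                 obsolete = length(obsolete),
                 alt_ids = length(alt_map),
                 dropped_cross_namespace = dropped_cross_ns,
                 dropped_obsolete_edge = dropped_obsolete_parent,
                 dropped_other_namespace = dropped_other_ns)
  go_dag(terms = ids, name = nm, namespace = ns,
         edges = data.frame(child = e_child, parent = e_parent, relation = e_rel,
                            stringsAsFactors = FALSE),
         alt_ids = alt_map, obsolete = obsolete, report = report)
}

# accept a file path or a vector of lines
read_text_input <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Serialise a GO DAG back to OBO text
#'
#' Produces OBO 1.2 text that [parse_obo()] reads back into an identical
#' `go_dag` (round-trip identity); stanzas and lines are emitted in sorted
#' order so the output is a deterministic function of the graph.
#'
#' @param dag a [go_dag()] object.
#' @param file optional path; when given the lines are written there.
#' @param header extra comment lines (each prefixed `!`) placed after the
#'   format-version line, e.g. generator provenance.
#' @return Character vector of OBO lines, invisibly when `file` is given.
#' @export
emit_obo <- function(dag, file = NULL, header = character()) {
  out <- c("format-version: 1.2",
           if (length(header)) paste0("! ", header))
  for (t in dag$terms) {
    out <- c(out, "", "[Term]",
             paste0("id: ", t),
             paste0("name: ", dag$name[[t]]),
             paste0("namespace: ", ns_long_of[[dag$namespace[[t]]]]))
    alts <- sort(names(dag$alt_ids)[dag$alt_ids == t])
    out <- c(out, if (length(alts)) paste0("alt_id: ", alts))
    pa <- dag$parents_of[[t]]
    if (length(pa)) {
      ord <- order(names(pa))
      for (i in ord) {
        p <- names(pa)[i]; rel <- pa[[i]]
        out <- c(out, if (rel == "is_a") {
          paste0("is_a: ", p, " ! ", dag$name[[p]])
        } else {
          paste0("relationship: ", rel, " ", p, " ! ", dag$name[[p]])
        })
      }
    }
  }
  for (t in dag$obsolete) {
    out <- c(out, "", "[Term]",
             paste0("id: ", t),
             "name: obsolete term",
             "is_obsolete: true")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
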