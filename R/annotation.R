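# annotation module: GAF parsing and per-term annotation counts

#' Construct an annotation set
#'
#' @param records data frame with columns `gene`, `term`, `evidence`,
#'   `symbol` (one row per retained annotation).
#' @param namespace the single namespace (`BP`, `MF`, `CC`) the annotations
#'   were filtered to.
#' @param report optional list of parse counts.
#' @return Object of class `annotation_set` with elements `records`, `direct`
#'   (named list gene -> sorted unique term IDs), `symbol` (named character),
#'   `namespace` and `report`.
#' @export
annotation_set <- function(records, namespace, report = list()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term") %in% names(records)))
  if (!nrow(records)) stop("annotation set has no records", call. = FALSE)
  if (is.null(records$evidence)) records$evidence <- "IEA"
  if (is.null(records$symbol)) records$symbol <- records$gene
  records$term <- normalize_term_id(records$term)
  records <- unique(records[order(records$gene, records$term, records$evidence),
                            c("gene", "term", "evidence", "symbol")])
  rownames(records) <- NULL
  direct <- lapply(split(records$term, records$gene), function(x) sort(unique(x)))
  symbol <- vapply(split(records$symbol, records$gene), `[[`, character(1), 1L)
  structure(list(records = records, direct = direct, symbol = symbol,
                 namespace = normalize_namespace(namespace), report = report),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$direct), "genes,", nrow(x$records),
      "annotations, namespace", x$namespace, "\n")
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Applies the standard GAF filters: comment lines (`!`) are ignored; rows
#' with fewer than 15 tab-separated columns are skipped and counted; rows
#' whose qualifier contains `NOT` are dropped; rows whose evidence code is in
#' `evidence_exclude` are dropped; rows whose term is obsolete, absent from
#' the DAG, or outside the requested namespace are dropped with a logged
#' count. Alternative term IDs are mapped to primary IDs. Gene identity is
#' the DB object ID (column 2); the symbol (column 3) is kept for display.
#'
#' @param x path to a GAF file, or a character vector of GAF lines.
#' @param dag the [go_dag()] the annotations refer to.
#' @param namespace namespace to keep; defaults to the DAG's namespace when
#'   the DAG holds a single one.
#' @param evidence_exclude character vector of evidence codes to drop
#'   (default empty: keep all, including IEA).
#' @return An [annotation_set()]; its `report` counts retained and dropped
#'   rows by reason.
#' @export
parse_gaf <- function(x, dag, namespace = NULL, evidence_exclude = character()) {
  lines <- read_text_input(x)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]

  if (is.null(namespace)) {
    if (length(dag$roots) != 1L) {
      stop("dag holds several namespaces; pass `namespace` explicitly",
           call. = FALSE)
    }
    namespace <- names(dag$roots)
  }
  namespace <- normalize_namespace(namespace)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  malformed <- sum(n_col < 15L)
  fields <- fields[n_col >= 15L]

  gene <- vapply(fields, `[[`, character(1), 2L)
  symbol <- vapply(fields, `[[`, character(1), 3L)
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  term <- vapply(fields, `[[`, character(1), 5L)
  evidence <- vapply(fields, `[[`, character(1), 7L)

  dropped_not <- grepl("(^|\\|)NOT($|\\|)", qualifier)
  dropped_evidence <- evidence %in% evidence_exclude

  term_norm <- rep(NA_character_, length(term))
  ok_syntax <- grepl("^go:[0-9]{7}$", trimws(term), ignore.case = TRUE)
  term_norm[ok_syntax] <- normalize_term_id(term[ok_syntax])
  hit <- match(term_norm, names(dag$alt_ids))
  term_norm[!is.na(hit)] <- unname(dag$alt_ids[hit[!is.na(hit)]])

  is_obsolete <- term_norm %in% dag$obsolete
  in_dag <- term_norm %in% dag$terms
  in_ns <- in_dag & dag$namespace[term_norm] == namespace

  keep <- !dropped_not & !dropped_evidence & !is_obsolete & in_ns
  report <- list(rows = length(lines),
                 retained = sum(keep),
                 malformed = malformed,
                 dropped_not = sum(dropped_not),
                 dropped_evidence = sum(dropped_evidence & !dropped_not),
                 dropped_obsolete = sum(is_obsolete & !dropped_not & !dropped_evidence),
                 dropped_unknown_term = sum(!in_dag & !is_obsolete & !dropped_not & !dropped_evidence),
                 dropped_other_namespace = sum(in_dag & !in_ns & !dropped_not & !dropped_evidence))
  if (!sum(keep)) stop("no annotation rows retained after filtering", call. = FALSE)
  annotation_set(
    data.frame(gene = gene[keep], term = term_norm[keep],
               evidence = evidence[keep], symbol = symbol[keep],
               stringsAsFactors = FALSE),
    namespace = namespace, report = report)
}

#' Serialise an annotation set to GAF 2.2 text
#'
#' Emits one row per (gene, term, evidence) record in sorted order, so the
#' output is deterministic and [parse_gaf()] on it reproduces the input set.
#'
#' @param annset an [annotation_set()].
#' @param file optional path to write to.
#' @param header extra comment lines (each prefixed `!`).
#' @return Character vector of GAF lines, invisibly when `file` is given.
#' @export
emit_gaf <- function(annset, file = NULL, header = character()) {
  aspect <- c(BP = "P", MF = "F", CC = "C")[[annset$namespace]]
  r <- annset$records
  rows <- paste(
    "SGT", r$gene, r$symbol, "involved_in", r$term, "SGT_REF:0000001",
    r$evidence, "", aspect, "", "", "protein", "taxon:0000", "20160101",
    "SGT", "", "",
    sep = "\t")
  out <- c("!gaf-version: 2.2", if (length(header)) paste0("! ", header), rows)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Per-term annotation counts
#'
#' `direct` counts the distinct genes directly annotated to each term.
#' `closure` is the numerator of the term-probability formula: in the default
#' `"literal"` mode it is the direct count of the term plus the *sum* of
#' direct counts over all strict descendants (a gene annotated to two
#' descendants contributes twice); in `"distinct"` mode it is the number of
#' distinct genes annotated to the term or any descendant.
#'
#' @param annset an [annotation_set()].
#' @param dag the matching [go_dag()].
#' @param mode `"literal"` (default) or `"distinct"`.
#' @return Object of class `term_counts`: list with named integer vectors
#'   `direct` and `closure` over all DAG terms, and the `mode` used.
#' @export
term_counts <- function(annset, dag, mode = c("literal", "distinct")) {
  mode <- match.arg(mode)
  if (length(dag$roots) != 1L || names(dag$roots) != annset$namespace) {
    stop("annotation namespace (", annset$namespace,
         ") does not match the dag", call. = FALSE)
  }
  direct <- stats::setNames(integer(length(dag$terms)), dag$terms)
  per_term <- split(annset$records$gene, annset$records$term)
  n_distinct <- vapply(per_term, function(g) length(unique(g)), integer(1))
  direct[names(n_distinct)] <- n_distinct

  closure <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  if (mode == "literal") {
    for (t in names(n_distinct)) {
      a <- ancestors(dag, t)
      closure[a] <- closure[a] + direct[[t]]
    }
  } else {
    for (g in names(annset$direct)) {
      cl <- unique(unlist(lapply(annset$direct[[g]], ancestors, dag = dag),
                          use.names = FALSE))
      closure[cl] <- closure[cl] + 1
    }
  }
  structure(list(direct = direct, closure = closure, mode = mode),
            class = "term_counts")
}
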