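# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so generators are
#' reproducible without clobbering the session RNG state.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# GO identifiers are compared case-sensitively after normalising the prefix
# to upper case; anything not of the form GO: + 7 digits is rejected.
normalize_term_id <- function(id) {
  id <- sub("^go:", "GO:", trimws(id), ignore.case = TRUE)
  bad <- !grepl("^GO:[0-9]{7}$", id)
  if (any(bad)) {
    stop("malformed term identifier(s): ", paste(unique(id[bad]), collapse = ", "),
         call. = FALSE)
  }
  id
}

# 17 significant digits: enough to round-trip any IEEE double through text
fmt_real <- function(x) sprintf("%.17g", x)

ns_long_of <- c(BP = "biological_process", MF = "molecular_function",
                CC = "cellular_component")
ns_short_of <- c(biological_process = "BP", molecular_function = "MF",
                 cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC",
                 P = "BP", F = "MF", C = "CC")

normalize_namespace <- function(ns) {
  out <- unname(ns_short_of[ns])
  if (any(is.na(out))) {
    stop("unknown namespace: ", paste(unique(ns[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}
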