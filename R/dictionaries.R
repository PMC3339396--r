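# Multi-level entity dictionaries: load, merge, query.
#
# A dictionary is a tibble with columns term / accession / level / source and
# a "role" attribute saying whether its matches feed interaction extraction
# or context-vector counting. Terms are stored normalised (lowercase,
# whitespace collapsed); one term may map to several accessions, possibly at
# different levels, and one accession may have many synonym terms.

new_entity_dictionary <- function(df, role) {
  structure(
    as_tibble(df),
    role = role,
    class = c("entity_dictionary", class(as_tibble(df)))
  )
}

#' Build an entity dictionary from vectors
#'
#' Programmatic constructor used by the synthetic-world generator and tests;
#' [read_dictionary()] is the file-based equivalent.
#'
#' @param term Character vector of surface terms (normalised on construction).
#' @param accession Character vector of accession IDs.
#' @param level Character vector of entity levels (see [entity_levels()]).
#' @param source Source tag; recycled. Defaults to `"user"`.
#' @param role Either `"interaction"` (matches feed interaction extraction)
#'   or `"context"` (matches feed context vectors).
#' @return An `entity_dictionary`: a tibble with columns `term`, `accession`,
#'   `level`, `source` and a `role` attribute.
#' @export
#' @examples
#' entity_dictionary(c("donepezil", "ACHE"), c("D1", "G1"),
#'                   c("drug", "gene"), role = "interaction")
entity_dictionary <- function(term, accession, level, source = "user",
                              role = c("interaction", "context")) {
  role <- match.arg(role)
  assert_levels(level, "dictionary")
  df <- tibble(
    term = normalize_term(term),
    accession = as.character(accession),
    level = as.character(level),
    source = rep_len(as.character(source), length(term))
  )
  if (any(!nzchar(df$term))) {
    stop("dictionary terms must be non-empty after normalisation", call. = FALSE)
  }
  new_entity_dictionary(dplyr::distinct(df), role)
}

#' Read an entity dictionary from a TSV file
#'
#' The file is tab-separated UTF-8 with columns term / accession / level and
#' an optional fourth column source; by default there is no header line.
#' Terms are normalised with [normalize_term()]. Rows whose level is not one
#' of [entity_levels()], or with an empty term or accession, are skipped with
#' a warning giving the count.
#'
#' @param path Path to the TSV file.
#' @inheritParams entity_dictionary
#' @param header If `TRUE`, skip the first line as a header.
#' @return An `entity_dictionary` tibble.
#' @export
read_dictionary <- function(path, role = c("interaction", "context"),
                            header = FALSE) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop(sprintf("dictionary file not found: %s", path), call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    skip = if (header) 1L else 0L,
    progress = FALSE
  ))
  if (nrow(raw) == 0) {
    warning(sprintf("dictionary file is empty: %s", path), call. = FALSE)
    return(new_entity_dictionary(
      tibble(term = character(), accession = character(),
             level = character(), source = character()),
      role
    ))
  }
  if (ncol(raw) < 3) {
    stop(sprintf("dictionary file must have >= 3 tab-separated columns: %s", path),
         call. = FALSE)
  }
  df <- tibble(
    term = normalize_term(raw[[1]]),
    accession = raw[[2]],
    level = tolower(trimws(ifelse(is.na(raw[[3]]), "", raw[[3]]))),
    source = if (ncol(raw) >= 4) dplyr::coalesce(raw[[4]], "unknown") else "unknown"
  )
  ok <- nzchar(df$term) & !is.na(df$accession) & nzchar(df$accession) &
    df$level %in% entity_levels()
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed dictionary row(s) in %s", n_bad, path),
            call. = FALSE)
  }
  new_entity_dictionary(dplyr::distinct(df[ok, ]), role)
}

#' Write an entity dictionary to TSV
#'
#' Inverse of [read_dictionary()] (no header): reading the written file back
#' reproduces the entry set.
#'
#' @param dict An `entity_dictionary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path) {
  readr::write_tsv(
    as_tibble(dict)[, c("term", "accession", "level", "source")],
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Dictionary role
#'
#' @param dict An `entity_dictionary`.
#' @return `"interaction"` or `"context"`.
#' @export
dict_role <- function(dict) attr(dict, "role")

#' Merge two entity dictionaries
#'
#' Set union on (term, accession, level, source). Both dictionaries must
#' have the same role: merging an interaction dictionary with a context
#' dictionary is an error, since their matches feed different pipeline
#' stages.
#'
#' @param x,y `entity_dictionary` objects with equal roles.
#' @return The merged `entity_dictionary`.
#' @export
merge_dictionaries <- function(x, y) {
  if (!identical(dict_role(x), dict_role(y))) {
    stop(sprintf("cannot merge dictionaries with roles '%s' and '%s'",
                 dict_role(x), dict_role(y)), call. = FALSE)
  }
  new_entity_dictionary(
    dplyr::distinct(dplyr::bind_rows(as_tibble(x), as_tibble(y))),
    dict_role(x)
  )
}

#' Look up a term in a dictionary
#'
#' Exact match on the normalised term. A term may resolve to several
#' accessions, possibly at different levels (the ambiguity is retained;
#' downstream pattern filters resolve usage).
#'
#' @param dict An `entity_dictionary`.
#' @param term A single term (normalised before lookup).
#' @return A tibble with columns `accession` and `level`; zero rows when the
#'   term is absent.
#' @export
#' @examples
#' d <- entity_dictionary("donepezil", "D1", "drug")
#' dict_lookup(d, "DONEPEZIL")
dict_lookup <- function(dict, term) {
  stopifnot(length(term) == 1)
  key <- normalize_term(term)
  df <- as_tibble(dict)
  hits <- df[df$term == key, ]
  dplyr::distinct(tibble(accession = hits$accession, level = hits$level))
}

#' @export
print.entity_dictionary <- function(x, ...) {
  cat(sprintf("<entity_dictionary> role=%s, %d entries, %d accessions\n",
              dict_role(x), nrow(x), dplyr::n_distinct(x$accession)))
  NextMethod()
}
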