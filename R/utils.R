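# Shared constants and small helpers.

#' Entity levels recognised by the package
#'
#' The four biomedical entity levels used throughout: `drug`, `gene`,
#' `disease` and `symptom`. Drug-gene and gene-disease pairs drive
#' interaction extraction; all four levels may contribute context terms.
#'
#' @export
entity_levels <- function() c("drug", "gene", "disease", "symptom")

# ordering used to canonicalise interaction pairs: drug < gene < disease < symptom
level_rank <- function(level) {
  match(level, entity_levels())
}

#' Normalise an entity term
#'
#' Lowercases, collapses internal whitespace and strips leading/trailing
#' whitespace. This is the normalisation applied to dictionary terms on load
#' and to query terms in [dict_lookup()].
#'
#' @param x Character vector of terms.
#' @return Character vector of normalised terms.
#' @export
#' @examples
#' normalize_term("  Nerve  Growth Factor ")
normalize_term <- function(x) {
  stringr::str_squish(tolower(x))
}

# Key used for text matching: like normalize_term() but treats every
# non-alphanumeric character as a separator, so "beta-peptide" and
# "beta peptide" collapse to the same token sequence.
match_key <- function(x) {
  stringr::str_squish(gsub("[^[:alnum:]]+", " ", tolower(x)))
}

#' Canonical key for an unordered accession pair
#'
#' Orders the two accessions lexicographically and joins them, so that
#' (D1, Z1) and (Z1, D1) map to the same key. Used to match inferred
#' drug-disease pairs against the gold standard.
#'
#' @param a,b Character vectors of accession IDs (recycled).
#' @return Character vector of canonical pair keys.
#' @export
canonical_pair <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

assert_levels <- function(level, where = "input") {
  bad <- setdiff(unique(level), entity_levels())
  if (length(bad) > 0) {
    stop(sprintf("%s contains unknown entity levels: %s",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(level)
}
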