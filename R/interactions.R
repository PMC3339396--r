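# Interaction extraction and per-interaction context vectors.
#
# An interaction is an unordered typed accession pair restricted to the
# drug-gene and gene-disease patterns. Its frequency counts sentence-level
# co-occurrence incidences: each sentence containing both members adds one,
# regardless of how many times either member is mentioned in that sentence.
# The support set collects the abstracts contributing at least one such
# sentence.

admissible_pair <- function(level1, level2) {
  (level1 == "drug" & level2 == "gene") |
    (level1 == "gene" & level2 == "disease")
}

#' Extract typed co-occurrence interactions
#'
#' For every sentence, every pair of distinct tagged entities whose levels
#' form a drug-gene or gene-disease pattern contributes one co-occurrence
#' incidence to that pair. Pairs are canonicalised with the lower level rank
#' first (drug before gene, gene before disease), so `acc1`/`level1` is
#' always the drug of a drug-gene pair and the gene of a gene-disease pair.
#'
#' @param mentions Mentions tibble from [tag_corpus()]; only
#'   `role == "interaction"` rows are used.
#' @return A tibble with one row per interaction: `interaction_id`
#'   (`"acc1|acc2"`), `acc1`, `level1`, `acc2`, `level2`, `frequency`
#'   (sentence co-occurrence count), `support` (list column of abstract
#'   ids), `n_abstracts`.
#' @export
extract_interactions <- function(mentions) {
  im <- dplyr::filter(mentions, .data$role == "interaction")
  empty <- tibble(
    interaction_id = character(), acc1 = character(), level1 = character(),
    acc2 = character(), level2 = character(), frequency = integer(),
    support = list(), n_abstracts = integer()
  )
  if (nrow(im) == 0) return(empty)

  per_sent <- dplyr::distinct(im, .data$abstract_id, .data$sentence_index,
                              .data$accession, .data$level)
  pairs <- dplyr::inner_join(
    per_sent, per_sent,
    by = c("abstract_id", "sentence_index"),
    suffix = c("1", "2"),
    relationship = "many-to-many"
  )
  pairs <- dplyr::filter(
    pairs,
    level_rank(.data$level1) < level_rank(.data$level2),
    admissible_pair(.data$level1, .data$level2),
    .data$accession1 != .data$accession2
  )
  if (nrow(pairs) == 0) return(empty)

  pairs |>
    dplyr::group_by(acc1 = .data$accession1, level1 = .data$level1,
                    acc2 = .data$accession2, level2 = .data$level2) |>
    dplyr::summarise(
      frequency = dplyr::n(),
      support = list(sort(unique(.data$abstract_id))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_abstracts = lengths(.data$support),
      interaction_id = paste(.data$acc1, .data$acc2, sep = "|")
    ) |>
    dplyr::arrange(.data$interaction_id) |>
    dplyr::select("interaction_id", "acc1", "level1", "acc2", "level2",
                  "frequency", "support", "n_abstracts")
}

#' Write interactions to TSV
#'
#' Columns: acc1, level1, acc2, level2, frequency, n_abstracts (the support
#' list column is summarised by its size).
#'
#' @param interactions Tibble from [extract_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  readr::write_tsv(
    dplyr::select(interactions, "acc1", "level1", "acc2", "level2",
                  "frequency", "n_abstracts"),
    path, progress = FALSE
  )
  invisible(path)
}

#' Build averaged context vectors per interaction
#'
#' The context vector of an interaction is the average, over its supporting
#' abstracts, of the abstract-level context-term counts: for each term t,
#' `value[t] = sum over supporting abstracts of count(t) / n_abstracts`.
#' Supporting abstracts with no context mentions still contribute to the
#' denominator. By default context terms equal to either interaction member
#' accession are excluded, so an interaction's members never inflate its own
#' similarity; set `include_self_terms = TRUE` to keep them.
#'
#' Vectors are kept sparse: a term absent from the result has value 0 over
#' the global context vocabulary.
#'
#' @param interactions Tibble from [extract_interactions()].
#' @param context_counts Per-abstract counts from [count_context_terms()].
#' @param include_self_terms Keep member accessions as context terms?
#' @return A `context_vectors` object: a long tibble `interaction_id`,
#'   `term`, `value` whose attributes record the covered interaction ids and
#'   the observed context vocabulary.
#' @export
build_context_vectors <- function(interactions, context_counts,
                                  include_self_terms = FALSE) {
  if (any(interactions$n_abstracts < 1)) {
    stop("interaction with empty support set; context vectors undefined",
         call. = FALSE)
  }
  vocabulary <- sort(unique(context_counts$accession))
  base <- dplyr::select(interactions, "interaction_id", "acc1", "acc2",
                        "n_abstracts", "support")
  long <- tidyr::unnest(base, "support") |>
    dplyr::rename(abstract_id = "support") |>
    dplyr::inner_join(context_counts, by = "abstract_id",
                      relationship = "many-to-many")
  if (!include_self_terms) {
    long <- dplyr::filter(long, .data$accession != .data$acc1,
                          .data$accession != .data$acc2)
  }
  vals <- long |>
    dplyr::group_by(.data$interaction_id, term = .data$accession) |>
    dplyr::summarise(total = sum(.data$count), n_abstracts = .data$n_abstracts[1],
                     .groups = "drop") |>
    dplyr::mutate(value = .data$total / .data$n_abstracts) |>
    dplyr::select("interaction_id", "term", "value") |>
    dplyr::arrange(.data$interaction_id, .data$term)
  structure(
    vals,
    interaction_ids = sort(unique(interactions$interaction_id)),
    vocabulary = vocabulary,
    class = c("context_vectors", class(vals))
  )
}

#' Context vocabulary of a set of context vectors
#'
#' The global context vocabulary recorded when the vectors were built (all
#' context-term accessions observed in the corpus, whether or not they
#' appear in any particular vector).
#'
#' @param cv A `context_vectors` object.
#' @return Sorted character vector of term accessions.
#' @export
context_vocabulary <- function(cv) {
  attr(cv, "vocabulary") %||% sort(unique(cv$term))
}

#' Extract one interaction's context vector
#'
#' @param cv A `context_vectors` object.
#' @param interaction_id Interaction key (`"acc1|acc2"`).
#' @return Named numeric vector of term averages (sparse: absent terms are
#'   implicitly 0).
#' @export
cv_vector <- function(cv, interaction_id) {
  covered <- attr(cv, "interaction_ids")
  if (!is.null(covered) && !(interaction_id %in% covered)) {
    stop(sprintf("no context vector for interaction '%s'", interaction_id),
         call. = FALSE)
  }
  rows <- cv[cv$interaction_id == interaction_id, ]
  stats::setNames(rows$value, rows$term)
}

#' Write context vectors as sparse TSV triples
#'
#' @param cv A `context_vectors` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_vectors <- function(cv, path) {
  readr::write_tsv(as_tibble(cv), path, progress = FALSE)
  invisible(path)
}
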