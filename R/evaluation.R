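# Precision-at-k evaluation against a gold-standard drug-disease pair set.

#' Read a gold-standard pair file
#'
#' Two-column TSV of accession IDs (drug, disease in either order). Pairs
#' are canonicalised with [canonical_pair()] and deduplicated, so a pair
#' listed in both orders counts once. Malformed rows (fewer than two
#' non-empty fields) are skipped with a warning.
#'
#' @param path Path to the TSV file.
#' @param header If `TRUE`, skip the first line.
#' @return A `gold_standard` tibble with columns `acc1`, `acc2`,
#'   `pair_key`.
#' @export
read_gold <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("gold-standard file not found: %s", path), call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    skip = if (header) 1L else 0L,
    progress = FALSE
  ))
  if (nrow(raw) == 0) {
    warning(sprintf("gold-standard file is empty: %s", path), call. = FALSE)
    return(gold_standard(character(), character()))
  }
  if (ncol(raw) < 2) {
    warning(sprintf("gold-standard rows need 2 columns; none usable in %s", path),
            call. = FALSE)
    return(gold_standard(character(), character()))
  }
  a <- trimws(dplyr::coalesce(raw[[1]], ""))
  b <- trimws(dplyr::coalesce(raw[[2]], ""))
  ok <- nzchar(a) & nzchar(b)
  if (any(!ok)) {
    warning(sprintf("skipped %d malformed gold-standard row(s) in %s",
                    sum(!ok), path), call. = FALSE)
  }
  gold_standard(a[ok], b[ok])
}

#' Construct a gold standard from accession pairs
#'
#' @param acc1,acc2 Character vectors of paired accessions.
#' @return A `gold_standard` tibble `acc1`, `acc2`, `pair_key`,
#'   deduplicated on the canonical key.
#' @export
gold_standard <- function(acc1, acc2) {
  df <- tibble(acc1 = as.character(acc1), acc2 = as.character(acc2)) |>
    dplyr::mutate(pair_key = canonical_pair(.data$acc1, .data$acc2)) |>
    dplyr::distinct(.data$pair_key, .keep_all = TRUE)
  structure(df, class = c("gold_standard", class(df)))
}

#' Precision at k
#'
#' Fraction of the top-k ranked relations whose (drug, disease) pair is in
#' the gold standard. The denominator is always `k`, even when fewer than k
#' relations exist, so short rankings are penalised consistently.
#'
#' @param ranked Ranked relations from [rank_relations()] (needs columns
#'   `drug`, `disease`, ordered by rank).
#' @param gold A `gold_standard` object.
#' @param k Cutoff, `>= 1`.
#' @return Precision in \[0, 1\].
#' @export
precision_at_k <- function(ranked, gold, k) {
  stopifnot(length(k) == 1, k >= 1)
  if (nrow(ranked) == 0) {
    warning("empty ranking: precision is 0", call. = FALSE)
    return(0)
  }
  top <- utils::head(ranked, k)
  hits <- sum(canonical_pair(top$drug, top$disease) %in% gold$pair_key)
  hits / k
}

#' Evaluate all four score rankings at several cutoffs
#'
#' Ranks the relations by each requested score and computes precision@k for
#' every cutoff, yielding the score-by-cutoff precision table.
#'
#' @param relations An `inferred_relations` tibble from [score_relations()].
#' @param gold A `gold_standard` object.
#' @param scores Score names to rank by.
#' @param ks Integer vector of cutoffs.
#' @return A tibble `score`, `k`, `precision`.
#' @export
evaluate_rankings <- function(relations, gold,
                              scores = c("baseline", "sum", "max", "hybrid"),
                              ks = c(100, 500, 1000)) {
  scores <- match.arg(scores, several.ok = TRUE)
  grid <- tidyr::expand_grid(score = scores, k = as.integer(ks))
  grid$precision <- purrr::map2_dbl(grid$score, grid$k, function(s, k) {
    precision_at_k(rank_relations(relations, s), gold, k)
  })
  grid
}

#' Plot a precision table
#'
#' Grouped bar chart of precision@k by scoring method, one panel-free view
#' mirroring the usual ABC-model comparison figures.
#'
#' @param precision A tibble `score`, `k`, `precision` from
#'   [evaluate_rankings()].
#' @return A ggplot object.
#' @export
plot_precision <- function(precision) {
  ggplot2::ggplot(
    precision,
    ggplot2::aes(x = factor(.data$k),
                 y = .data$precision,
                 fill = .data$score)
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "top k", y = "precision@k", fill = "score") +
    ggplot2::theme_minimal()
}
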