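# ABC join and scoring of inferred drug-disease relations.
#
# Given drug-gene (A-B) and gene-disease (B-C) interactions, every shared
# bridge gene B yields a candidate A-C relation. Each bridge carries the
# similarity between the context vectors of its two interactions; a bridge
# is "meaningful" when that similarity strictly exceeds the threshold tau.
# Four scores per (A, C) pair:
#   baseline: sum over ALL bridges of freq(A-B) * freq(B-C)   (frequency ABC)
#   sum:      sum over meaningful bridges of similarity
#   max:      max over meaningful bridges of similarity (0 if none)
#   hybrid:   sum over meaningful bridges of freq(A-B) * freq(B-C)

#' Enumerate A-B-C triples
#'
#' Joins drug-gene interactions to gene-disease interactions on the bridge
#' gene. Every (drug A, gene B, disease C) combination for which both
#' interactions exist yields one triple.
#'
#' @param interactions Tibble from [extract_interactions()].
#' @return A tibble `drug`, `gene`, `disease`, `freq_ab`, `freq_bc`,
#'   `id_ab`, `id_bc`, ordered by (drug, gene, disease).
#' @export
abc_join <- function(interactions) {
  dg <- interactions |>
    dplyr::filter(.data$level1 == "drug", .data$level2 == "gene") |>
    dplyr::select(drug = "acc1", gene = "acc2", freq_ab = "frequency",
                  id_ab = "interaction_id")
  gd <- interactions |>
    dplyr::filter(.data$level1 == "gene", .data$level2 == "disease") |>
    dplyr::select(gene = "acc1", disease = "acc2", freq_bc = "frequency",
                  id_bc = "interaction_id")
  dplyr::inner_join(dg, gd, by = "gene", relationship = "many-to-many") |>
    dplyr::select("drug", "gene", "disease", "freq_ab", "freq_bc",
                  "id_ab", "id_bc") |>
    dplyr::arrange(.data$drug, .data$gene, .data$disease)
}

#' Aggregate a relation's bridges into the four scores
#'
#' Pure scoring kernel shared by [score_relations()]: given the bridges of
#' one candidate relation it returns the baseline, sum, max and hybrid
#' scores. `NA` similarities (undefined Spearman) are never meaningful.
#'
#' @param sim Numeric vector of per-bridge similarities.
#' @param freq_ab,freq_bc Integer vectors of per-bridge interaction
#'   frequencies.
#' @param tau Meaningfulness threshold; a bridge counts when `sim > tau`
#'   (strict).
#' @return A one-row tibble `baseline`, `sum`, `max`, `hybrid`,
#'   `n_meaningful`.
#' @export
#' @examples
#' score_bridges(sim = c(0.96, 0.5), freq_ab = c(3, 10),
#'               freq_bc = c(2, 10), tau = 0.95)
score_bridges <- function(sim, freq_ab, freq_bc, tau) {
  stopifnot(length(sim) == length(freq_ab), length(sim) == length(freq_bc))
  meaningful <- !is.na(sim) & sim > tau
  prod <- as.numeric(freq_ab) * as.numeric(freq_bc)
  tibble(
    baseline = sum(prod),
    sum = if (any(meaningful)) sum(sim[meaningful]) else 0,
    max = if (any(meaningful)) max(sim[meaningful]) else 0,
    hybrid = sum(prod[meaningful]),
    n_meaningful = sum(meaningful)
  )
}

#' Score inferred drug-disease relations
#'
#' Computes the context similarity of every bridge (A-B vs B-C context
#' vectors), aggregates bridges per distinct (drug, disease) pair with
#' [score_bridges()], and returns one row per candidate relation.
#' Relations with no meaningful bridge are retained with similarity-based
#' scores of 0, so the baseline and filtered rankings cover the same
#' candidate universe.
#'
#' @param triples Tibble from [abc_join()].
#' @param cv A `context_vectors` object covering every interaction in
#'   `triples` (a missing vector is an error naming the interaction).
#' @param measure `"cosine"` or `"spearman"`.
#' @param tau Meaningfulness threshold (strict `>`); defaults to
#'   [default_similarity_threshold()] for the chosen measure
#'   (`"pharmgkb"` setting).
#' @param vocabulary Vocabulary for Spearman densification; defaults to
#'   [context_vocabulary()] of `cv`.
#' @return An `inferred_relations` tibble: `drug`, `disease`, `n_bridges`,
#'   `n_meaningful`, `baseline`, `sum`, `max`, `hybrid`,
#'   `best_bridge_gene`, `best_bridge_sim`, `bridges` (list column of
#'   per-bridge tibbles), with attributes `measure` and `tau`.
#' @export
score_relations <- function(triples, cv, measure = c("cosine", "spearman"),
                            tau = NULL, vocabulary = NULL) {
  measure <- match.arg(measure)
  tau <- tau %||% default_similarity_threshold(measure, "pharmgkb")
  vocabulary <- vocabulary %||% context_vocabulary(cv)

  empty <- tibble(
    drug = character(), disease = character(), n_bridges = integer(),
    n_meaningful = integer(), baseline = numeric(), sum = numeric(),
    max = numeric(), hybrid = numeric(), best_bridge_gene = character(),
    best_bridge_sim = numeric(), bridges = list()
  )
  if (nrow(triples) == 0) {
    return(structure(empty, measure = measure, tau = tau,
                     class = c("inferred_relations", class(empty))))
  }

  covered <- attr(cv, "interaction_ids")
  if (!is.null(covered)) {
    missing <- setdiff(unique(c(triples$id_ab, triples$id_bc)), covered)
    if (length(missing) > 0) {
      stop(sprintf("missing context vector(s) for interaction(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }

  # cache each interaction's sparse vector once
  ids <- unique(c(triples$id_ab, triples$id_bc))
  by_id <- split(cv[, c("term", "value")], factor(cv$interaction_id, levels = ids))
  vecs <- lapply(by_id, function(d) stats::setNames(d$value, d$term))

  sims <- vapply(seq_len(nrow(triples)), function(k) {
    u <- vecs[[triples$id_ab[k]]]
    v <- vecs[[triples$id_bc[k]]]
    if (measure == "cosine") {
      cosine_similarity(u, v)
    } else {
      suppressWarnings(spearman_similarity(u, v, vocabulary))
    }
  }, numeric(1))

  scored <- triples |>
    dplyr::mutate(sim = sims) |>
    dplyr::group_by(.data$drug, .data$disease) |>
    dplyr::arrange(.data$gene, .by_group = TRUE) |>
    dplyr::summarise(
      n_bridges = dplyr::n(),
      scores = list(score_bridges(.data$sim, .data$freq_ab, .data$freq_bc, tau)),
      best_bridge_gene = best_bridge(.data$gene, .data$sim, tau)$gene,
      best_bridge_sim = best_bridge(.data$gene, .data$sim, tau)$sim,
      bridges = list(tibble(gene = gene, sim = sim,
                            freq_ab = freq_ab, freq_bc = freq_bc,
                            meaningful = !is.na(sim) & sim > tau)),
      .groups = "drop"
    ) |>
    tidyr::unnest("scores") |>
    dplyr::select("drug", "disease", "n_bridges", "n_meaningful",
                  "baseline", "sum", "max", "hybrid",
                  "best_bridge_gene", "best_bridge_sim", "bridges") |>
    dplyr::arrange(.data$drug, .data$disease)

  structure(scored, measure = measure, tau = tau,
            class = c("inferred_relations", class(scored)))
}

# gene and similarity of the best meaningful bridge (first gene on ties);
# NA gene / 0 sim when no bridge is meaningful
best_bridge <- function(gene, sim, tau) {
  ok <- !is.na(sim) & sim > tau
  if (!any(ok)) return(list(gene = NA_character_, sim = 0))
  best <- which(ok)[which.max(sim[ok])]
  list(gene = gene[best], sim = sim[best])
}

#' Rank inferred relations by one score
#'
#' Descending by the chosen score; ties broken ascending by (drug accession,
#' disease accession), so the order is deterministic and stable across
#' reruns.
#'
#' @param relations An `inferred_relations` tibble from [score_relations()].
#' @param score One of `"baseline"`, `"sum"`, `"max"`, `"hybrid"`.
#' @return The relations tibble with columns `rank`, `score_name`, `score`
#'   prepended, ordered by rank.
#' @export
rank_relations <- function(relations,
                           score = c("hybrid", "baseline", "sum", "max")) {
  score <- match.arg(score)
  relations |>
    as_tibble() |>
    dplyr::arrange(dplyr::desc(.data[[score]]), .data$drug, .data$disease) |>
    dplyr::mutate(rank = dplyr::row_number(), score_name = score,
                  score = .data[[score]]) |>
    dplyr::select("rank", "drug", "disease", "score_name", "score",
                  dplyr::everything())
}

#' Write a ranked relation list to TSV
#'
#' @param ranked Output of [rank_relations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path) {
  readr::write_tsv(
    dplyr::select(ranked, "rank", "drug", "disease", "score_name", "score",
                  "n_bridges", "best_bridge_gene", "best_bridge_sim"),
    path, progress = FALSE
  )
  invisible(path)
}
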