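# End-to-end pipeline: tag -> extract -> vectors -> infer -> rank -> evaluate.

#' Run the full context-vector ABC pipeline
#'
#' Executes every stage in order on in-memory inputs: sentence splitting,
#' interaction- and context-role tagging, interaction extraction, context
#' vector construction, the ABC join, bridge scoring, ranking by each
#' requested score, and (when a gold standard is supplied) precision@k
#' evaluation. Per-stage counts are logged with `message()` when `verbose`.
#'
#' @param corpus A tibble `id`, `text` (see [read_corpus()]).
#' @param interaction_dict An `entity_dictionary` with role
#'   `"interaction"`.
#' @param context_dict An `entity_dictionary` with role `"context"`.
#' @param gold Optional `gold_standard` for evaluation.
#' @param measure `"cosine"` or `"spearman"`.
#' @param tau Meaningfulness threshold; default per
#'   [default_similarity_threshold()].
#' @param scores Scores to rank by.
#' @param ks Precision cutoffs.
#' @param include_self_terms Passed to [build_context_vectors()].
#' @param exclude_direct Drop candidate (drug, disease) pairs that already
#'   co-occur in a corpus sentence (classical open-discovery filtering);
#'   off by default.
#' @param verbose Log per-stage counts to stderr.
#' @return An `lbd_result` list with elements `sentences`, `mentions`,
#'   `context_counts`, `interactions`, `context_vectors`, `triples`,
#'   `relations`, `rankings` (named list of ranked tibbles), `precision`
#'   (or `NULL`), `counts`, `measure`, `tau`.
#' @export
run_pipeline <- function(corpus, interaction_dict, context_dict, gold = NULL,
                         measure = c("cosine", "spearman"), tau = NULL,
                         scores = c("baseline", "sum", "max", "hybrid"),
                         ks = c(100, 500, 1000),
                         include_self_terms = FALSE, exclude_direct = FALSE,
                         verbose = FALSE) {
  measure <- match.arg(measure)
  tau <- tau %||% default_similarity_threshold(measure, "pharmgkb")
  say <- function(...) if (verbose) message(sprintf(...))

  say("corpus: %d abstracts", nrow(corpus))
  sentences <- split_sentences(corpus)
  say("sentences: %d", nrow(sentences))

  m_int <- tag_corpus(corpus, interaction_dict, sentences)
  m_ctx <- tag_corpus(corpus, context_dict, sentences)
  mentions <- dplyr::bind_rows(m_int, m_ctx)
  say("mentions: %d interaction-role, %d context-role", nrow(m_int), nrow(m_ctx))

  context_counts <- count_context_terms(m_ctx)
  interactions <- extract_interactions(m_int)
  say("interactions: %d (%d drug-gene, %d gene-disease)",
      nrow(interactions),
      sum(interactions$level1 == "drug"),
      sum(interactions$level1 == "gene"))

  cv <- build_context_vectors(interactions, context_counts,
                              include_self_terms = include_self_terms)
  triples <- abc_join(interactions)
  say("triples: %d", nrow(triples))

  relations <- score_relations(triples, cv, measure = measure, tau = tau)
  if (exclude_direct) {
    direct <- direct_pairs(m_int)
    before <- nrow(relations)
    keep <- !(canonical_pair(relations$drug, relations$disease) %in% direct)
    relations <- relations[keep, ]
    say("excluded %d direct drug-disease pairs", before - nrow(relations))
  }
  say("relations: %d candidate drug-disease pairs", nrow(relations))

  rankings <- lapply(stats::setNames(scores, scores), function(s) {
    rank_relations(relations, s)
  })
  precision <- NULL
  if (!is.null(gold)) {
    precision <- evaluate_rankings(relations, gold, scores = scores, ks = ks)
    say("evaluated against %d gold pairs", nrow(gold))
  }

  structure(
    list(
      sentences = sentences, mentions = mentions,
      context_counts = context_counts, interactions = interactions,
      context_vectors = cv, triples = triples, relations = relations,
      rankings = rankings, precision = precision,
      counts = tibble(
        n_abstracts = nrow(corpus), n_sentences = nrow(sentences),
        n_mentions = nrow(mentions), n_interactions = nrow(interactions),
        n_triples = nrow(triples), n_relations = nrow(relations)
      ),
      measure = measure, tau = tau
    ),
    class = "lbd_result"
  )
}

# canonical keys of drug-disease pairs that co-occur directly in a sentence
direct_pairs <- function(interaction_mentions) {
  per_sent <- dplyr::distinct(interaction_mentions, .data$abstract_id,
                              .data$sentence_index, .data$accession,
                              .data$level)
  dd <- dplyr::inner_join(
    per_sent, per_sent,
    by = c("abstract_id", "sentence_index"),
    suffix = c("1", "2"), relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$level1 == "drug", .data$level2 == "disease",
                  .data$accession1 != .data$accession2)
  unique(canonical_pair(dd$accession1, dd$accession2))
}

#' @export
print.lbd_result <- function(x, ...) {
  cat(sprintf(
    "<lbd_result> %s (tau=%g): %d abstracts -> %d interactions -> %d relations\n",
    x$measure, x$tau, x$counts$n_abstracts, x$counts$n_interactions,
    x$counts$n_relations
  ))
  if (!is.null(x$precision)) {
    print(tidyr::pivot_wider(x$precision, names_from = "k",
                             values_from = "precision", names_prefix = "p@"))
  }
  invisible(x)
}

#' Tidy a pipeline result into its ranked relation table
#'
#' @param x An `lbd_result`.
#' @param score Which ranking to return.
#' @param ... Unused.
#' @return The ranked relations tibble for the chosen score.
#' @method tidy lbd_result
#' @export
tidy.lbd_result <- function(x, score = "hybrid", ...) {
  x$rankings[[score]] %||% rank_relations(x$relations, score)
}

#' One-row summary of a pipeline result
#'
#' @param x An `lbd_result`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts plus measure and threshold.
#' @method glance lbd_result
#' @export
glance.lbd_result <- function(x, ...) {
  dplyr::mutate(x$counts, measure = x$measure, tau = x$tau)
}

#' Plot the precision table of a pipeline result
#'
#' @param object An `lbd_result` run with a gold standard.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lbd_result
#' @export
autoplot.lbd_result <- function(object, ...) {
  if (is.null(object$precision)) {
    stop("result has no precision table; run the pipeline with a gold standard",
         call. = FALSE)
  }
  plot_precision(object$precision)
}

#' Read a pipeline run configuration
#'
#' YAML file with keys: `corpus` (path), `corpus_format`,
#' `interaction_dictionary`, `context_dictionary`, `gold` (paths),
#' `header` (dictionaries/gold have a header line), `measure`,
#' `threshold`, `scores`, `ks`, `include_self_terms`, `exclude_direct`,
#' `out_dir`, `seed`. Missing keys take the defaults shown by
#' [run_pipeline()].
#'
#' @param path Path to the YAML file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    corpus_format = "jsonl", header = FALSE, measure = "cosine",
    threshold = NULL, scores = c("baseline", "sum", "max", "hybrid"),
    ks = c(100, 500, 1000), include_self_terms = FALSE,
    exclude_direct = FALSE, out_dir = ".", seed = 1L
  )
  utils::modifyList(defaults, cfg)
}

#' Run the pipeline from files and persist every stage
#'
#' File-based front end used by the command-line script: reads the inputs
#' named in the configuration, runs [run_pipeline()], and writes mentions,
#' interactions, context vectors, one ranked TSV per score, the precision
#' table (when a gold standard is configured) and a JSON run summary into
#' `out_dir`.
#'
#' @param config A list from [read_run_config()] (or equivalent).
#' @return The `lbd_result`, invisibly; `config$out_dir` holds the
#'   artefacts.
#' @export
run_pipeline_files <- function(config) {
  for (key in c("corpus", "interaction_dictionary", "context_dictionary")) {
    if (is.null(config[[key]])) {
      stop(sprintf("config is missing required key '%s'", key), call. = FALSE)
    }
    if (!file.exists(config[[key]])) {
      stop(sprintf("input file for '%s' not found: %s", key, config[[key]]),
           call. = FALSE)
    }
  }
  if (!is.null(config$gold) && !file.exists(config$gold)) {
    stop(sprintf("gold-standard file not found: %s", config$gold), call. = FALSE)
  }
  corpus <- read_corpus(config$corpus, format = config$corpus_format)
  idict <- read_dictionary(config$interaction_dictionary, "interaction",
                           header = isTRUE(config$header))
  cdict <- read_dictionary(config$context_dictionary, "context",
                           header = isTRUE(config$header))
  gold <- if (!is.null(config$gold)) {
    read_gold(config$gold, header = isTRUE(config$header))
  }
  res <- run_pipeline(
    corpus, idict, cdict, gold = gold,
    measure = config$measure, tau = config$threshold,
    scores = config$scores, ks = config$ks,
    include_self_terms = isTRUE(config$include_self_terms),
    exclude_direct = isTRUE(config$exclude_direct),
    verbose = TRUE
  )
  out <- config$out_dir %||% "."
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  write_mentions(res$mentions, file.path(out, "mentions.tsv"))
  write_interactions(res$interactions, file.path(out, "interactions.tsv"))
  write_context_vectors(res$context_vectors, file.path(out, "context_vectors.tsv"))
  for (s in names(res$rankings)) {
    write_ranked(res$rankings[[s]], file.path(out, sprintf("ranked_%s.tsv", s)))
  }
  if (!is.null(res$precision)) {
    readr::write_tsv(res$precision, file.path(out, "precision.tsv"),
                     progress = FALSE)
  }
  jsonlite::write_json(
    c(as.list(glance(res)), list(scores = names(res$rankings))),
    file.path(out, "run_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}
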