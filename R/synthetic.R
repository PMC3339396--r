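# Synthetic test worlds with planted A-B-C chains.
#
# A world is a self-contained set of inputs (entity dictionaries, abstract
# corpus, gold standard) plus a truth manifest. Each chain plants one
# drug-gene and one gene-disease interaction, realised as templated
# abstracts with exactly one co-occurrence sentence each, so the planted
# sentence frequency equals the number of abstracts. Coherent chains draw
# the context terms of both interactions from one shared concentrated
# multinomial; decoy chains use two disjoint signature distributions and
# inflated frequencies, so they dominate a frequency-only ranking but fail
# the context-similarity filter.

#' Configuration for a synthetic world
#'
#' Defaults are the package's reference study conditions: 10 coherent and
#' 10 decoy chains over 25 drugs/genes/diseases, a 40-term symptom context
#' vocabulary, 3 abstracts per coherent interaction with 6 context draws
#' each, context coherence 0.95, and a 5x frequency multiplier for decoys.
#'
#' @param n_drugs,n_genes,n_diseases Entity pool sizes (each >= total
#'   chains; every chain uses a distinct drug, gene and disease).
#' @param n_context_terms Size of the symptom-level context vocabulary
#'   (>= 6, so a decoy chain can hold two disjoint 3-term signatures).
#' @param n_coherent_chains,n_decoy_chains Numbers of planted chains
#'   (>= 0, total >= 1).
#' @param abstracts_per_interaction Abstracts generated per coherent
#'   interaction; decoys get this times `decoy_frequency_multiplier`.
#' @param context_terms_per_abstract Context-term draws per abstract.
#' @param coherence Probability in \[0, 1\] that a context draw comes from
#'   the chain's signature distribution rather than the uniform background.
#' @param decoy_frequency_multiplier Frequency inflation factor (>= 1) for
#'   decoy chains.
#' @param seed Integer RNG seed; the world is a pure function of the
#'   configuration including the seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 25, n_genes = 25, n_diseases = 25,
                             n_context_terms = 40,
                             n_coherent_chains = 10, n_decoy_chains = 10,
                             abstracts_per_interaction = 3,
                             context_terms_per_abstract = 6,
                             coherence = 0.95,
                             decoy_frequency_multiplier = 5,
                             seed = 1L) {
  cfg <- list(
    n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
    n_diseases = as.integer(n_diseases),
    n_context_terms = as.integer(n_context_terms),
    n_coherent_chains = as.integer(n_coherent_chains),
    n_decoy_chains = as.integer(n_decoy_chains),
    abstracts_per_interaction = as.integer(abstracts_per_interaction),
    context_terms_per_abstract = as.integer(context_terms_per_abstract),
    coherence = as.numeric(coherence),
    decoy_frequency_multiplier = as.numeric(decoy_frequency_multiplier),
    seed = as.integer(seed)
  )
  n_chains <- cfg$n_coherent_chains + cfg$n_decoy_chains
  if (cfg$n_drugs < 1 || cfg$n_genes < 1 || cfg$n_diseases < 1 ||
      cfg$n_context_terms < 6 || cfg$abstracts_per_interaction < 1 ||
      cfg$context_terms_per_abstract < 1) {
    stop("synthetic_config: entity/abstract counts out of range", call. = FALSE)
  }
  if (cfg$n_coherent_chains < 0 || cfg$n_decoy_chains < 0 || n_chains < 1) {
    stop("synthetic_config: need at least one chain", call. = FALSE)
  }
  if (n_chains > min(cfg$n_drugs, cfg$n_genes, cfg$n_diseases)) {
    stop("synthetic_config: more chains than available drugs/genes/diseases",
         call. = FALSE)
  }
  if (cfg$coherence < 0 || cfg$coherence > 1) {
    stop("synthetic_config: coherence must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$decoy_frequency_multiplier < 1) {
    stop("synthetic_config: decoy_frequency_multiplier must be >= 1",
         call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# two surface synonyms per accession, e.g. "drug007" and "drug007 ii"
synthetic_surfaces <- function(prefix, n) {
  stem <- sprintf("%s%03d", prefix, seq_len(n))
  list(syn1 = stem, syn2 = paste(stem, "ii"))
}

#' Generate a synthetic world
#'
#' Builds dictionaries, corpus, gold standard and truth manifest for the
#' given configuration; fully reproducible from the seed. Every abstract
#' has three sentences: a title mentioning one member, one interaction
#' sentence containing both members (the single co-occurrence sentence),
#' and one sentence carrying the drawn context terms. Entity surfaces
#' alternate randomly between two synonyms to exercise synonym collapsing;
#' the context dictionary spans symptom terms plus the gene and disease
#' vocabularies (multi-level context).
#'
#' @param config A `synthetic_config`.
#' @param dir Optional directory; when given, the world is also written as
#'   `dictionary_interaction.tsv`, `dictionary_context.tsv`,
#'   `corpus.jsonl`, `gold.tsv` and `manifest.tsv`.
#' @return A `synthetic_world` list: `config`, `interaction_dict`,
#'   `context_dict`, `corpus`, `gold`, `manifest`, and `paths` when `dir`
#'   was given.
#' @export
generate_world <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::local_seed(config$seed)

  drugs <- sprintf("D%03d", seq_len(config$n_drugs))
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  diseases <- sprintf("Z%03d", seq_len(config$n_diseases))
  ctx <- sprintf("S%03d", seq_len(config$n_context_terms))

  surf <- list(
    drug = synthetic_surfaces("drug", config$n_drugs),
    gene = synthetic_surfaces("gene", config$n_genes),
    disease = synthetic_surfaces("dis", config$n_diseases),
    symptom = synthetic_surfaces("sym", config$n_context_terms)
  )
  accs <- list(drug = drugs, gene = genes, disease = diseases, symptom = ctx)

  dict_of <- function(levels, role) {
    parts <- lapply(levels, function(lv) {
      tibble(
        term = c(surf[[lv]]$syn1, surf[[lv]]$syn2),
        accession = rep(accs[[lv]], 2),
        level = lv
      )
    })
    all <- dplyr::bind_rows(parts)
    entity_dictionary(all$term, all$accession, all$level,
                      source = "synthetic", role = role)
  }
  interaction_dict <- dict_of(c("drug", "gene", "disease"), "interaction")
  context_dict <- dict_of(c("symptom", "gene", "disease"), "context")

  # one surface form for a mention, picking a synonym at random
  render <- function(level, acc) {
    i <- match(acc, accs[[level]])
    if (stats::runif(1) < 0.5) surf[[level]]$syn1[i] else surf[[level]]$syn2[i]
  }

  n_chains <- config$n_coherent_chains + config$n_decoy_chains
  chain_drug <- sample(drugs, n_chains)
  chain_gene <- sample(genes, n_chains)
  chain_disease <- sample(diseases, n_chains)
  chain_type <- rep(c("coherent", "decoy"),
                    c(config$n_coherent_chains, config$n_decoy_chains))

  freq_coherent <- config$abstracts_per_interaction
  freq_decoy <- max(1L, as.integer(round(
    config$abstracts_per_interaction * config$decoy_frequency_multiplier
  )))

  draw_context <- function(sig) {
    n <- config$context_terms_per_abstract
    from_sig <- stats::runif(n) < config$coherence
    out <- character(n)
    if (any(from_sig)) out[from_sig] <- sample(sig, sum(from_sig), replace = TRUE)
    if (any(!from_sig)) out[!from_sig] <- sample(ctx, sum(!from_sig), replace = TRUE)
    out
  }

  abstracts <- list()
  manifest_rows <- list()
  counter <- 0L
  for (k in seq_len(n_chains)) {
    type <- chain_type[k]
    a <- chain_drug[k]; b <- chain_gene[k]; c_ <- chain_disease[k]
    if (type == "coherent") {
      sig_ab <- sort(sample(ctx, 3))
      sig_bc <- sig_ab
      freq <- freq_coherent
    } else {
      both <- sample(ctx, 6)
      sig_ab <- sort(both[1:3])
      sig_bc <- sort(both[4:6])
      freq <- freq_decoy
    }
    for (side in c("ab", "bc")) {
      sig <- if (side == "ab") sig_ab else sig_bc
      for (r in seq_len(freq)) {
        counter <- counter + 1L
        ctx_terms <- draw_context(sig)
        ctx_surfaces <- vapply(ctx_terms, function(t) render("symptom", t),
                               character(1))
        if (side == "ab") {
          title <- sprintf("Observations regarding %s.", render("gene", b))
          body <- sprintf("The agent %s modulates %s under the studied condition.",
                          render("drug", a), render("gene", b))
        } else {
          title <- sprintf("Observations regarding %s.", render("disease", c_))
          body <- sprintf("The factor %s is associated with %s in patients.",
                          render("gene", b), render("disease", c_))
        }
        ctx_sentence <- sprintf("Patients also showed %s.",
                                paste(ctx_surfaces, collapse = " and "))
        abstracts[[counter]] <- tibble(
          id = sprintf("SYN%05d", counter),
          text = paste(title, body, ctx_sentence)
        )
      }
    }
    manifest_rows[[k]] <- tibble(
      chain = k, type = type, drug = a, gene = b, disease = c_,
      freq_ab = freq, freq_bc = freq,
      context_ab = paste(sig_ab, collapse = ","),
      context_bc = paste(sig_bc, collapse = ",")
    )
  }

  corpus <- dplyr::bind_rows(abstracts)
  manifest <- dplyr::bind_rows(manifest_rows)
  gold_tbl <- manifest |>
    dplyr::filter(.data$type == "coherent") |>
    dplyr::select("drug", "disease")
  gold <- gold_standard(gold_tbl$drug, gold_tbl$disease)

  world <- structure(
    list(config = config, interaction_dict = interaction_dict,
         context_dict = context_dict, corpus = corpus, gold = gold,
         manifest = manifest),
    class = "synthetic_world"
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      interaction_dict = file.path(dir, "dictionary_interaction.tsv"),
      context_dict = file.path(dir, "dictionary_context.tsv"),
      corpus = file.path(dir, "corpus.jsonl"),
      gold = file.path(dir, "gold.tsv"),
      manifest = file.path(dir, "manifest.tsv")
    )
    write_dictionary(interaction_dict, paths$interaction_dict)
    write_dictionary(context_dict, paths$context_dict)
    write_corpus(corpus, paths$corpus)
    readr::write_tsv(gold_tbl, paths$gold, col_names = FALSE, progress = FALSE)
    readr::write_tsv(manifest, paths$manifest, progress = FALSE)
    world$paths <- paths
  }
  world
}

#' Truth manifest of a synthetic world
#'
#' One row per planted chain: type (coherent/decoy), the A/B/C accessions,
#' the planted per-interaction frequencies and the signature context terms
#' of each interaction.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @return The manifest tibble.
#' @export
truth_manifest <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  world$manifest
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d abstracts, %d chains (%d coherent, %d decoy), seed %d\n",
    nrow(x$corpus), nrow(x$manifest),
    sum(x$manifest$type == "coherent"), sum(x$manifest$type == "decoy"),
    x$config$seed
  ))
  invisible(x)
}
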