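# Dictionary-based entity tagging.
#
# Matching is token-boundary constrained: a mention may not start or end in
# the middle of a word, so "ache" never matches inside "headache". Within a
# sentence the tagger scans tokens left to right and takes the longest
# dictionary term starting at the current token (greedy longest match);
# matched tokens are consumed, which keeps same-role mentions in a sentence
# non-overlapping. Both the dictionary term and the text are tokenised on
# non-alphanumeric characters, so hyphen/space variants of a synonym match.

# term-key -> tibble(accession, level) hash index, plus max key token length
build_dict_index <- function(dict) {
  df <- as_tibble(dict)
  keys <- match_key(df$term)
  keep <- nzchar(keys)
  df <- df[keep, ]
  keys <- keys[keep]
  idx <- new.env(hash = TRUE, parent = emptyenv())
  split_rows <- split(seq_len(nrow(df)), keys)
  for (k in names(split_rows)) {
    rows <- df[split_rows[[k]], c("accession", "level")]
    assign(k, dplyr::distinct(rows), envir = idx)
  }
  max_len <- if (length(keys) == 0) 0L else max(lengths(strsplit(names(split_rows), " ", fixed = TRUE)))
  list(index = idx, max_len = max_len)
}

# token positions within one text: start, end (1-based inclusive), lower string
tokenize_text <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1) {
    return(list(start = integer(0), end = integer(0), lower = character(0)))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  list(start = start, end = end,
       lower = tolower(substring(text, start, end)))
}

#' Tag a corpus with an entity dictionary
#'
#' Runs the greedy left-to-right longest-match tagger over every sentence of
#' every abstract. Each match emits one mention row per (accession, level)
#' pair the matched term maps to; all rows of one run carry the dictionary's
#' role. Spans are 1-based inclusive character positions into the abstract
#' text and always lie inside their sentence span; `surface` is the exact
#' text slice.
#'
#' @param corpus A tibble with columns `id`, `text` (see [read_corpus()]).
#' @param dict An `entity_dictionary`.
#' @param sentences Optional precomputed sentence spans from
#'   [split_sentences()]; computed on the fly when missing.
#' @return A tibble of mentions: `abstract_id`, `sentence_index`, `start`,
#'   `end`, `surface`, `accession`, `level`, `role`.
#' @export
#' @examples
#' corp <- tibble::tibble(id = "1", text = "Donepezil inhibits ACHE.")
#' dict <- entity_dictionary(c("donepezil", "ache"), c("D1", "G1"),
#'                           c("drug", "gene"), role = "interaction")
#' tag_corpus(corp, dict)
tag_corpus <- function(corpus, dict, sentences = NULL) {
  if (nrow(as_tibble(dict)) == 0) {
    stop("cannot tag with an empty dictionary", call. = FALSE)
  }
  role <- dict_role(dict)
  sentences <- sentences %||% split_sentences(corpus)
  built <- build_dict_index(dict)
  idx <- built$index
  max_len <- built$max_len
  sent_by_abs <- split(sentences, sentences$abstract_id)

  # flat accumulators; one row per (match, accession-level) pair
  o_aid <- list(); o_sent <- list(); o_start <- list(); o_end <- list()
  o_surf <- list(); o_acc <- list(); o_lvl <- list()
  p <- 0L
  for (i in seq_len(nrow(corpus))) {
    aid <- corpus$id[i]
    text <- corpus$text[i]
    sents <- sent_by_abs[[aid]]
    if (is.null(sents)) next
    toks <- tokenize_text(text)
    if (length(toks$start) == 0) next
    for (s in seq_len(nrow(sents))) {
      in_sent <- which(toks$start >= sents$start[s] & toks$end <= sents$end[s])
      n <- length(in_sent)
      j <- 1L
      while (j <= n) {
        matched <- 0L
        hits <- NULL
        for (L in seq(min(max_len, n - j + 1L), 1L)) {
          ids <- in_sent[j:(j + L - 1L)]
          key <- paste(toks$lower[ids], collapse = " ")
          h <- get0(key, envir = idx, inherits = FALSE)
          if (!is.null(h)) {
            matched <- L
            hits <- h
            break
          }
        }
        if (matched > 0L) {
          ids <- in_sent[j:(j + matched - 1L)]
          m_start <- toks$start[ids[1]]
          m_end <- toks$end[ids[length(ids)]]
          k <- nrow(hits)
          p <- p + 1L
          o_aid[[p]] <- rep(aid, k)
          o_sent[[p]] <- rep(sents$sentence_index[s], k)
          o_start[[p]] <- rep(m_start, k)
          o_end[[p]] <- rep(m_end, k)
          o_surf[[p]] <- rep(substr(text, m_start, m_end), k)
          o_acc[[p]] <- hits$accession
          o_lvl[[p]] <- hits$level
          j <- j + matched
        } else {
          j <- j + 1L
        }
      }
    }
  }
  if (p == 0L) {
    return(tibble(abstract_id = character(), sentence_index = integer(),
                  start = integer(), end = integer(), surface = character(),
                  accession = character(), level = character(),
                  role = character()))
  }
  tibble(
    abstract_id = unlist(o_aid, use.names = FALSE),
    sentence_index = unlist(o_sent, use.names = FALSE),
    start = unlist(o_start, use.names = FALSE),
    end = unlist(o_end, use.names = FALSE),
    surface = unlist(o_surf, use.names = FALSE),
    accession = unlist(o_acc, use.names = FALSE),
    level = unlist(o_lvl, use.names = FALSE),
    role = role
  )
}

#' Count context terms per abstract
#'
#' Counts context-role mentions per (abstract, accession) across the whole
#' abstract (context aggregation is at abstract level, not sentence level).
#' Synonyms collapse because the count key is the accession ID.
#'
#' @param mentions Mentions tibble from [tag_corpus()].
#' @param abstract_id Optional single id restricting the result to one
#'   abstract.
#' @return A tibble `abstract_id`, `accession`, `count`.
#' @export
count_context_terms <- function(mentions, abstract_id = NULL) {
  ctx <- dplyr::filter(mentions, .data$role == "context")
  if (!is.null(abstract_id)) {
    ctx <- dplyr::filter(ctx, .data$abstract_id == !!abstract_id)
  }
  if (nrow(ctx) == 0) {
    return(tibble(abstract_id = character(), accession = character(),
                  count = integer()))
  }
  dplyr::count(ctx, .data$abstract_id, .data$accession, name = "count")
}

#' Write mentions to TSV
#'
#' @param mentions Mentions tibble from [tag_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  readr::write_tsv(mentions, path, progress = FALSE)
  invisible(path)
}
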