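# Shared fixtures and independent brute-force oracles.
#
# The worked-example world plants two abstracts: one with interaction A:B and
# context terms a, b, a; one with interaction B:C and context terms a, c, c.
# It exercises counting, averaging and similarity on values small enough to
# verify by hand.

fig4_interaction_dict <- function() {
  entity_dictionary(
    term = c("entia", "entib", "entic"),
    accession = c("A", "B", "C"),
    level = c("drug", "gene", "disease"),
    role = "interaction"
  )
}

fig4_context_dict <- function() {
  entity_dictionary(
    term = c("terma", "termb", "termc"),
    accession = c("a", "b", "c"),
    level = "symptom",
    role = "context"
  )
}

fig4_corpus <- function() {
  tibble::tibble(
    id = c("Abstract1", "Abstract2"),
    text = c(
      "The agent entia binds entib. Patients showed terma and termb and terma.",
      "The factor entib binds entic. Patients showed terma and termc and termc."
    )
  )
}

# Small random dictionary for oracle tests. Multi-token synonyms never share
# their leading token with another term, so the greedy left-to-right rule and
# the longest-then-leftmost rule coincide (see tagging docs).
rand_test_dict <- function() {
  acc <- c(sprintf("D%02d", 1:4), sprintf("G%02d", 1:4), sprintf("Z%02d", 1:4))
  lvl <- rep(c("drug", "gene", "disease"), each = 4)
  stem <- c(sprintf("drg%02d", 1:4), sprintf("gen%02d", 1:4),
            sprintf("dis%02d", 1:4))
  entity_dictionary(
    term = c(stem, paste(stem, "form")),
    accession = rep(acc, 2),
    level = rep(lvl, 2),
    role = "interaction"
  )
}

# Random corpus over a dictionary's surfaces plus filler words.
rand_test_corpus <- function(dict, n_abstracts) {
  surfaces <- unique(dict$term)
  fillers <- c("binds", "with", "under", "cohort", "notably", "observed",
               "plasma", "level", "markedly")
  make_sentence <- function() {
    n <- sample(3:7, 1)
    words <- sample(c(surfaces, fillers), n, replace = TRUE,
                    prob = c(rep(2, length(surfaces)), rep(1, length(fillers))))
    s <- paste(words, collapse = " ")
    paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)), ".")
  }
  tibble::tibble(
    id = as.character(seq_len(n_abstracts)),
    text = vapply(seq_len(n_abstracts), function(i) {
      paste(vapply(seq_len(sample(1:3, 1)), function(j) make_sentence(),
                   character(1)), collapse = " ")
    }, character(1))
  )
}

# --- independent oracles ----------------------------------------------------

# Brute-force tagger: enumerate every token-window dictionary match in every
# sentence, then resolve overlaps by (longer first, then leftmost). Returns
# one row per (match, accession, level).
oracle_tag <- function(corpus, dict) {
  sentences <- split_sentences(corpus)
  d <- tibble::as_tibble(dict)
  d$key <- gsub("[^[:alnum:] ]+", " ", tolower(d$term))
  d$key <- gsub("\\s+", " ", trimws(d$key))
  keys <- unique(d$key)
  max_len <- max(lengths(strsplit(keys, " ")))
  out <- list()
  for (i in seq_len(nrow(corpus))) {
    text <- corpus$text[i]
    sents <- sentences[sentences$abstract_id == corpus$id[i], ]
    m <- gregexpr("[[:alnum:]]+", text)[[1]]
    if (m[1] == -1) next
    tok_start <- as.integer(m)
    tok_end <- tok_start + attr(m, "match.length") - 1L
    tok_low <- tolower(substring(text, tok_start, tok_end))
    for (s in seq_len(nrow(sents))) {
      ids <- which(tok_start >= sents$start[s] & tok_end <= sents$end[s])
      n <- length(ids)
      if (n == 0) next
      cand <- list()
      for (a in seq_len(n)) {
        for (L in seq_len(min(max_len, n - a + 1))) {
          key <- paste(tok_low[ids[a:(a + L - 1)]], collapse = " ")
          if (key %in% keys) cand[[length(cand) + 1]] <- c(a, L)
        }
      }
      taken <- rep(FALSE, n)
      # longer first, then leftmost
      if (length(cand) > 0) {
        ord <- order(-vapply(cand, `[`, numeric(1), 2),
                     vapply(cand, `[`, numeric(1), 1))
        for (ci in ord) {
          a <- cand[[ci]][1]; L <- cand[[ci]][2]
          span <- a:(a + L - 1)
          if (any(taken[span])) next
          taken[span] <- TRUE
          key <- paste(tok_low[ids[span]], collapse = " ")
          hits <- unique(d[d$key == key, c("accession", "level")])
          out[[length(out) + 1]] <- data.frame(
            abstract_id = corpus$id[i],
            sentence_index = sents$sentence_index[s],
            start = tok_start[ids[a]],
            end = tok_end[ids[a + L - 1]],
            accession = hits$accession,
            level = hits$level
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(abstract_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(),
                      accession = character(), level = character()))
  }
  do.call(rbind, out)
}

# Brute-force interaction recount: nested loops over sentences and mention
# pairs, one incidence per sentence containing both members.
oracle_interactions <- function(mentions) {
  counts <- list()
  support <- list()
  key_of <- function(a1, a2) paste(a1, a2, sep = "|")
  sent_keys <- unique(mentions[, c("abstract_id", "sentence_index")])
  for (r in seq_len(nrow(sent_keys))) {
    rows <- mentions[mentions$abstract_id == sent_keys$abstract_id[r] &
                       mentions$sentence_index == sent_keys$sentence_index[r], ]
    ents <- unique(rows[, c("accession", "level")])
    if (nrow(ents) < 2) next
    seen <- character(0)
    for (p in seq_len(nrow(ents))) {
      for (q in seq_len(nrow(ents))) {
        if (p == q) next
        lp <- ents$level[p]; lq <- ents$level[q]
        ok <- (lp == "drug" && lq == "gene") || (lp == "gene" && lq == "disease")
        if (!ok) next
        if (ents$accession[p] == ents$accession[q]) next
        k <- key_of(ents$accession[p], ents$accession[q])
        if (k %in% seen) next  # one incidence per sentence per pair
        seen <- c(seen, k)
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
        support[[k]] <- union(support[[k]] %||% character(0),
                              sent_keys$abstract_id[r])
      }
    }
  }
  if (length(counts) == 0) {
    return(data.frame(interaction_id = character(), frequency = integer(),
                      n_abstracts = integer()))
  }
  data.frame(
    interaction_id = names(counts),
    frequency = unlist(counts, use.names = FALSE),
    n_abstracts = lengths(support)[names(counts)],
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force ABC enumeration: double loop over interaction rows.
oracle_triples <- function(interactions) {
  out <- list()
  for (p in seq_len(nrow(interactions))) {
    for (q in seq_len(nrow(interactions))) {
      ab <- interactions[p, ]
      bc <- interactions[q, ]
      if (ab$level1 == "drug" && ab$level2 == "gene" &&
          bc$level1 == "gene" && bc$level2 == "disease" &&
          ab$acc2 == bc$acc1) {
        out[[length(out) + 1]] <- data.frame(
          drug = ab$acc1, gene = ab$acc2, disease = bc$acc2
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(drug = character(), gene = character(),
                      disease = character()))
  }
  do.call(rbind, out)
}
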