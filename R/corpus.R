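# Corpus I/O and sentence splitting.
#
# A corpus is a tibble with one row per abstract: columns `id` (PMID-like,
# unique) and `text` (title + abstract as one string). Sentence spans are a
# separate tibble keyed by abstract id, produced by split_sentences().

#' Read a corpus of abstracts
#'
#' Supports two formats. `"jsonl"`: one JSON object per line with keys `id`
#' and `text`. `"pubmed_xml"`: PubMed export XML; for each `PubmedArticle`
#' the PMID, `ArticleTitle` and all `AbstractText` elements are read, and
#' the title and abstract are concatenated into one text (separated by
#' `". "` unless the title already ends in terminal punctuation). Records
#' without abstract/text content are skipped with a warning; duplicate ids
#' keep the first occurrence with a warning.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` or `"pubmed_xml"`.
#' @return A tibble with columns `id` and `text`, in input order.
#' @export
read_corpus <- function(path, format = c("jsonl", "pubmed_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("corpus file not found: %s", path), call. = FALSE)
  }
  recs <- switch(format,
    jsonl = read_corpus_jsonl(path),
    pubmed_xml = read_corpus_pubmed_xml(path)
  )
  empty <- is.na(recs$text) | !nzchar(trimws(recs$text))
  if (any(empty)) {
    warning(sprintf("skipped %d record(s) without abstract text", sum(empty)),
            call. = FALSE)
    recs <- recs[!empty, ]
  }
  dup <- duplicated(recs$id)
  if (any(dup)) {
    warning(sprintf("duplicate abstract id(s) kept-first: %s",
                    paste(unique(recs$id[dup]), collapse = ", ")),
            call. = FALSE)
    recs <- recs[!dup, ]
  }
  recs
}

read_corpus_jsonl <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, function(l) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) {
      stop(sprintf("unparseable JSONL line in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    tibble(
      id = as.character(obj$id %||% NA_character_),
      text = as.character(obj$text %||% NA_character_)
    )
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    return(tibble(id = character(), text = character()))
  }
  if (anyNA(out$id)) stop(sprintf("JSONL record without id in %s", path), call. = FALSE)
  out
}

read_corpus_pubmed_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("unparseable XML corpus %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  recs <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- paste(
      xml2::xml_text(xml2::xml_find_all(a, ".//Abstract/AbstractText")),
      collapse = " "
    )
    tibble(id = pmid, text = join_title_abstract(title, abst))
  })
  dplyr::bind_rows(recs)
}

join_title_abstract <- function(title, abstract) {
  title <- trimws(ifelse(is.na(title), "", title))
  abstract <- trimws(ifelse(is.na(abstract), "", abstract))
  if (!nzchar(abstract)) return(NA_character_)
  if (!nzchar(title)) return(abstract)
  sep <- if (grepl("[.!?]$", title)) " " else ". "
  paste0(title, sep, abstract)
}

#' Write a corpus as JSONL
#'
#' One `{"id": ..., "text": ...}` object per line; reading the file back with
#' [read_corpus()] reproduces the (id, text) pairs.
#'
#' @param corpus A tibble with columns `id` and `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(id = corpus$id[i], text = corpus$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

# Abbreviations (lowercase, no dot) that do not terminate a sentence.
sentence_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "prof", "st", "vs", "fig", "figs",
    "al", "eg", "ie", "e", "i", "cf", "approx", "ca", "resp")
}

# Split one text into sentence spans (1-based inclusive [start, end]).
# Boundary rule: a run of . ! ? followed by whitespace and an uppercase
# letter or digit, unless the word immediately before the run is a known
# abbreviation. If no boundary is found the whole (trimmed) text is one span.
split_text_spans <- function(text) {
  stopifnot(length(text) == 1, nzchar(text))
  m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (k in seq_along(m)) {
      before <- substr(text, max(1L, m[k] - 30L), m[k] - 1L)
      word <- tolower(sub(".*?([[:alnum:]]+)$", "\\1", before))
      if (!grepl("[[:alnum:]]", before) || !(word %in% sentence_abbreviations())) {
        cuts <- c(cuts, ends[k])
      }
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  spans <- Map(function(s, e) trim_span(text, s, e), starts, stops)
  spans <- spans[!vapply(spans, is.null, logical(1))]
  if (length(spans) == 0) return(tibble(start = integer(), end = integer()))
  tibble(
    start = vapply(spans, `[[`, integer(1), 1),
    end = vapply(spans, `[[`, integer(1), 2)
  )
}

# shrink [s, e] to exclude leading/trailing whitespace; NULL if all whitespace
trim_span <- function(text, s, e) {
  while (s <= e && grepl("^\\s$", substr(text, s, s))) s <- s + 1L
  while (e >= s && grepl("^\\s$", substr(text, e, e))) e <- e - 1L
  if (s > e) NULL else c(s, e)
}

#' Split corpus texts into sentences
#'
#' Deterministic rule-based splitter: a sentence boundary is a run of
#' terminal punctuation (`.` `!` `?`) followed by whitespace and an
#' uppercase letter or digit, except after a small list of abbreviations
#' ("Dr.", "Fig.", "et al.", ...). Texts with no boundary yield a single
#' span. Spans are 1-based inclusive character ranges into the abstract
#' text, trimmed of surrounding whitespace; they are non-overlapping,
#' sorted, and jointly cover all non-whitespace characters.
#'
#' @param corpus A tibble with columns `id` and `text`.
#' @return A tibble with columns `abstract_id`, `sentence_index` (1-based),
#'   `start`, `end`.
#' @export
#' @examples
#' split_sentences(tibble::tibble(id = "1", text = "A b. C d."))
split_sentences <- function(corpus) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    spans <- split_text_spans(corpus$text[i])
    if (nrow(spans) == 0) return(NULL)
    tibble(
      abstract_id = corpus$id[i],
      sentence_index = seq_len(nrow(spans)),
      start = spans$start,
      end = spans$end
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(abstract_id = character(), sentence_index = integer(),
                  start = integer(), end = integer()))
  }
  res
}
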