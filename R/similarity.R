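# Context-vector similarity measures.
#
# Both measures compare two per-interaction context vectors expressed over
# the same global context vocabulary. Cosine works directly on the sparse
# representation. Spearman requires densifying over the vocabulary first,
# because zero-valued terms participate in rank ties; with a fixed global
# dimension the rank correlation is well defined and tie-corrected
# (fractional ranks, Pearson on ranks).

#' Cosine similarity of two sparse context vectors
#'
#' `sum(u_i v_i) / (||u|| ||v||)` over the shared vocabulary. Terms absent
#' from a sparse vector are 0, so only the intersection of the supports
#' contributes to the dot product. Returns 0 when either vector has zero
#' norm. For non-negative vectors the value lies in \[0, 1\].
#'
#' @param u,v Named numeric vectors (term -> value), as from [cv_vector()].
#' @return Cosine similarity in \[-1, 1\].
#' @export
#' @examples
#' cosine_similarity(c(a = 2, b = 1), c(a = 1, c = 2))  # 0.4
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  shared <- intersect(names(u), names(v))
  sum(u[shared] * v[shared]) / (nu * nv)
}

#' Spearman rank correlation of two context vectors
#'
#' The vectors are densified over `vocabulary` (absent terms become 0) and
#' the standard Spearman coefficient is computed: fractional ranks, then
#' Pearson correlation of the ranks, which reduces to
#' `1 - 6 * sum(d_i^2) / (n (n^2 - 1))` when no ranks are tied. Undefined
#' cases — fewer than two vocabulary terms, or a vector whose densified
#' values are all equal (zero rank variance) — return `NA` with a warning.
#'
#' @param u,v Named numeric vectors (term -> value).
#' @param vocabulary Ordered character vector of terms defining the shared
#'   dimension; defaults to the union of the two supports.
#' @return Spearman correlation in \[-1, 1\], or `NA` when undefined.
#' @export
#' @examples
#' spearman_similarity(c(a = 1, b = 2, c = 3), c(a = 1, b = 3, c = 2))  # 0.5
spearman_similarity <- function(u, v, vocabulary = NULL) {
  vocabulary <- vocabulary %||% sort(union(names(u), names(v)))
  n <- length(vocabulary)
  if (n < 2) {
    warning("Spearman undefined for vocabulary of size < 2", call. = FALSE)
    return(NA_real_)
  }
  du <- unname(ifelse(is.na(u[vocabulary]), 0, u[vocabulary]))
  dv <- unname(ifelse(is.na(v[vocabulary]), 0, v[vocabulary]))
  if (length(unique(du)) < 2 || length(unique(dv)) < 2) {
    warning("Spearman undefined: a vector is constant over the vocabulary",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(du, dv, method = "spearman")
}

#' Similarity between two interactions' context vectors
#'
#' @param cv A `context_vectors` object from [build_context_vectors()].
#' @param id1,id2 Interaction keys.
#' @param measure `"cosine"` or `"spearman"`.
#' @param vocabulary Vocabulary for Spearman densification; defaults to
#'   [context_vocabulary()] of `cv`.
#' @return The similarity value.
#' @export
context_similarity <- function(cv, id1, id2,
                               measure = c("cosine", "spearman"),
                               vocabulary = NULL) {
  measure <- match.arg(measure)
  u <- cv_vector(cv, id1)
  v <- cv_vector(cv, id2)
  switch(measure,
    cosine = cosine_similarity(u, v),
    spearman = spearman_similarity(u, v, vocabulary %||% context_vocabulary(cv))
  )
}

#' Default meaningfulness thresholds
#'
#' Reference threshold settings for the two similarity measures, as used in
#' the two evaluation settings of the underlying study design (a
#' PharmGKB-style and a CTD-style gold standard): cosine 0.945 / 0.95,
#' Spearman 0.999999999 / 0.999999998. A bridge is "meaningful" when its
#' similarity strictly exceeds the threshold.
#'
#' @param measure `"cosine"` or `"spearman"`.
#' @param setting `"pharmgkb"` or `"ctd"`.
#' @return The threshold value.
#' @export
default_similarity_threshold <- function(measure = c("cosine", "spearman"),
                                         setting = c("pharmgkb", "ctd")) {
  measure <- match.arg(measure)
  setting <- match.arg(setting)
  thresholds <- list(
    cosine = c(pharmgkb = 0.945, ctd = 0.95),
    spearman = c(pharmgkb = 0.999999999, ctd = 0.999999998)
  )
  unname(thresholds[[measure]][setting])
}
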