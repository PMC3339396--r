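tag_both <- function(corpus, idict = fig4_interaction_dict(),
                     cdict = fig4_context_dict()) {
  list(
    interaction = tag_corpus(corpus, idict),
    context = tag_corpus(corpus, cdict)
  )
}

test_that("only drug-gene and gene-disease sentence pairs are extracted", {
  corp <- tibble::tibble(id = "1", text = "Here entia entib entic co-occur.")
  m <- tag_corpus(corp, fig4_interaction_dict())
  ints <- extract_interactions(m)
  expect_equal(nrow(ints), 2)
  expect_setequal(ints$interaction_id, c("A|B", "B|C"))
  expect_equal(ints$frequency, c(1L, 1L))
  # no direct drug-disease pair
  expect_false("A|C" %in% ints$interaction_id)
})

test_that("frequency counts sentence incidences, support counts abstracts", {
  corp <- tibble::tibble(
    id = "1",
    text = "First entia binds entib. Then entia blocks entib again."
  )
  ints <- extract_interactions(tag_corpus(corp, fig4_interaction_dict()))
  expect_equal(ints$frequency, 2L)
  expect_equal(ints$n_abstracts, 1L)

  # repeated mentions within one sentence still count once
  corp2 <- tibble::tibble(id = "1", text = "Both entia and entia bind entib.")
  ints2 <- extract_interactions(tag_corpus(corp2, fig4_interaction_dict()))
  expect_equal(ints2$frequency, 1L)
})

test_that("sentences without an admissible level pair yield nothing", {
  dict <- entity_dictionary(c("drga", "drgb"), c("D1", "D2"),
                            c("drug", "drug"), role = "interaction")
  corp <- tibble::tibble(id = "1", text = "Only drga and drgb appear.")
  expect_equal(nrow(extract_interactions(tag_corpus(corp, dict))), 0)
})

test_that("single-abstract context vectors equal the abstract's count map", {
  corp <- fig4_corpus()
  m <- tag_both(corp)
  ints <- extract_interactions(m$interaction)
  cv <- build_context_vectors(ints, count_context_terms(m$context))
  ab <- cv_vector(cv, "A|B")
  expect_equal(ab[order(names(ab))], c(a = 2, b = 1))
  bc <- cv_vector(cv, "B|C")
  expect_equal(bc[order(names(bc))], c(a = 1, c = 2))
})

test_that("multi-abstract vectors average counts over the support", {
  ints <- tibble::tibble(
    interaction_id = "A|B", acc1 = "A", level1 = "drug",
    acc2 = "B", level2 = "gene", frequency = 2L,
    support = list(c("1", "2")), n_abstracts = 2L
  )
  counts <- tibble::tibble(
    abstract_id = c("1", "2", "2"),
    accession = c("a", "a", "c"),
    count = c(2L, 1L, 2L)
  )
  v <- cv_vector(build_context_vectors(ints, counts), "A|B")
  expect_equal(v[order(names(v))], c(a = 1.5, c = 1.0))

  # an abstract with no context mentions still dilutes the average
  counts3 <- counts[counts$abstract_id == "1", ]
  v3 <- cv_vector(build_context_vectors(ints, counts3), "A|B")
  expect_equal(v3, c(a = 1.0))
})

test_that("interaction members are excluded from their own context vector", {
  ints <- tibble::tibble(
    interaction_id = "A|B", acc1 = "A", level1 = "drug",
    acc2 = "B", level2 = "gene", frequency = 1L,
    support = list("1"), n_abstracts = 1L
  )
  counts <- tibble::tibble(abstract_id = "1", accession = c("A", "B"),
                           count = c(3L, 1L))
  v <- cv_vector(build_context_vectors(ints, counts), "A|B")
  expect_equal(length(v), 0)
  v2 <- cv_vector(build_context_vectors(ints, counts,
                                        include_self_terms = TRUE), "A|B")
  expect_equal(v2[order(names(v2))], c(A = 3, B = 1))
})

test_that("empty support is rejected", {
  ints <- tibble::tibble(
    interaction_id = "A|B", acc1 = "A", level1 = "drug",
    acc2 = "B", level2 = "gene", frequency = 1L,
    support = list(character(0)), n_abstracts = 0L
  )
  expect_error(build_context_vectors(ints, tibble::tibble(
    abstract_id = character(), accession = character(), count = integer()
  )), "empty support")
})

test_that("values are non-negative and bounded by the max single-abstract count", {
  withr::local_seed(11)
  w <- generate_world(synthetic_config(
    n_coherent_chains = 3, n_decoy_chains = 2, seed = 5
  ))
  mi <- tag_corpus(w$corpus, w$interaction_dict)
  mc <- tag_corpus(w$corpus, w$context_dict)
  counts <- count_context_terms(mc)
  cv <- build_context_vectors(extract_interactions(mi), counts)
  expect_true(all(cv$value >= 0))
  max_count <- tapply(counts$count, counts$accession, max)
  expect_true(all(cv$value <= max_count[cv$term] + 1e-12))
})
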