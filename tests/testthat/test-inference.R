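mk_interactions <- function(df) {
  # df: acc1, level1, acc2, level2, frequency
  dplyr::mutate(
    tibble::as_tibble(df),
    interaction_id = paste(acc1, acc2, sep = "|"),
    support = lapply(seq_len(nrow(df)), function(i) "1"),
    n_abstracts = 1L
  )
}

test_that("abc_join chains drug-gene with gene-disease on the bridge gene", {
  ints <- mk_interactions(data.frame(
    acc1 = c("D1", "G1"), level1 = c("drug", "gene"),
    acc2 = c("G1", "Z1"), level2 = c("gene", "disease"),
    frequency = c(2L, 3L)
  ))
  tr <- abc_join(ints)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$drug, "D1")
  expect_equal(tr$gene, "G1")
  expect_equal(tr$disease, "Z1")
  expect_equal(tr$freq_ab, 2L)
  expect_equal(tr$freq_bc, 3L)

  # no shared gene -> no triple
  ints2 <- mk_interactions(data.frame(
    acc1 = c("D1", "G2"), level1 = c("drug", "gene"),
    acc2 = c("G1", "Z1"), level2 = c("gene", "disease"),
    frequency = c(1L, 1L)
  ))
  expect_equal(nrow(abc_join(ints2)), 0)

  # two bridges for one (drug, disease) pair
  ints3 <- mk_interactions(data.frame(
    acc1 = c("D1", "D1", "G1", "G2"),
    level1 = c("drug", "drug", "gene", "gene"),
    acc2 = c("G1", "G2", "Z1", "Z1"),
    level2 = c("gene", "gene", "disease", "disease"),
    frequency = 1L
  ))
  expect_equal(nrow(abc_join(ints3)), 2)
})

test_that("abc_join matches a nested-loop oracle on random interaction sets", {
  withr::local_seed(17)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    is_dg <- sample(c(TRUE, FALSE), n, replace = TRUE)
    df <- data.frame(
      acc1 = ifelse(is_dg, sample(sprintf("D%d", 1:6), n, TRUE),
                    sample(sprintf("G%d", 1:5), n, TRUE)),
      level1 = ifelse(is_dg, "drug", "gene"),
      acc2 = ifelse(is_dg, sample(sprintf("G%d", 1:5), n, TRUE),
                    sample(sprintf("Z%d", 1:6), n, TRUE)),
      level2 = ifelse(is_dg, "gene", "disease"),
      frequency = sample(1:5, n, replace = TRUE)
    )
    df <- df[!duplicated(df[, c("acc1", "acc2")]), ]
    ints <- mk_interactions(df)
    got <- abc_join(ints)[, c("drug", "gene", "disease")]
    want <- oracle_triples(ints)
    want <- tibble::as_tibble(want[order(want$drug, want$gene, want$disease), ])
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("score_bridges evaluates the four scoring formulas", {
  s <- score_bridges(sim = c(0.96, 0.5), freq_ab = c(3, 10),
                     freq_bc = c(2, 10), tau = 0.95)
  expect_equal(s$baseline, 106)
  expect_equal(s$sum, 0.96)
  expect_equal(s$max, 0.96)
  expect_equal(s$hybrid, 6)

  # no meaningful bridge: similarity scores collapse to 0, baseline unchanged
  s0 <- score_bridges(sim = c(0.1, 0.2), freq_ab = c(3, 10),
                      freq_bc = c(2, 10), tau = 0.95)
  expect_equal(s0$baseline, 106)
  expect_equal(s0$sum, 0)
  expect_equal(s0$max, 0)
  expect_equal(s0$hybrid, 0)

  # threshold admitting every bridge makes hybrid equal baseline
  sall <- score_bridges(sim = c(0.96, 0.5), freq_ab = c(3, 10),
                        freq_bc = c(2, 10), tau = -1)
  expect_equal(sall$hybrid, sall$baseline)

  # NA similarity (undefined spearman) is never meaningful
  sna <- score_bridges(sim = c(NA, 0.99), freq_ab = c(2, 2),
                       freq_bc = c(2, 2), tau = 0.9)
  expect_equal(sna$hybrid, 4)
})

test_that("score_relations aggregates bridges per (drug, disease) pair", {
  m_ctx <- tag_corpus(fig4_corpus(), fig4_context_dict())
  ints <- extract_interactions(tag_corpus(fig4_corpus(),
                                          fig4_interaction_dict()))
  cv <- build_context_vectors(ints, count_context_terms(m_ctx))
  tr <- abc_join(ints)
  rel <- score_relations(tr, cv, measure = "cosine", tau = 0.3)
  expect_equal(nrow(rel), 1)
  expect_equal(rel$n_bridges, 1L)
  expect_equal(rel$baseline, 1)
  expect_equal(rel$sum, 0.4, tolerance = 1e-12)
  expect_equal(rel$best_bridge_gene, "B")
  # raising tau above the similarity removes the bridge but keeps the relation
  rel2 <- score_relations(tr, cv, measure = "cosine", tau = 0.5)
  expect_equal(rel2$hybrid, 0)
  expect_equal(rel2$baseline, 1)
  expect_true(is.na(rel2$best_bridge_gene))
})

test_that("score_relations errors on a missing context vector", {
  ints <- mk_interactions(data.frame(
    acc1 = c("D1", "G1"), level1 = c("drug", "gene"),
    acc2 = c("G1", "Z1"), level2 = c("gene", "disease"),
    frequency = 1L
  ))
  cv_partial <- structure(
    tibble::tibble(interaction_id = "D1|G1", term = "a", value = 1),
    interaction_ids = "D1|G1",
    vocabulary = "a",
    class = c("context_vectors", class(tibble::tibble()))
  )
  expect_error(score_relations(abc_join(ints), cv_partial), "G1\\|Z1")
})

test_that("scores are invariant to the input ordering of interactions", {
  w <- generate_world(synthetic_config(n_coherent_chains = 4,
                                       n_decoy_chains = 3, seed = 23))
  mi <- tag_corpus(w$corpus, w$interaction_dict)
  mc <- tag_corpus(w$corpus, w$context_dict)
  ints <- extract_interactions(mi)
  cv <- build_context_vectors(ints, count_context_terms(mc))
  rel1 <- score_relations(abc_join(ints), cv)
  withr::local_seed(2)
  shuffled <- ints[sample(nrow(ints)), ]
  rel2 <- score_relations(abc_join(shuffled), cv)
  expect_equal(tibble::as_tibble(rel1), tibble::as_tibble(rel2))
})

test_that("ranking is descending with deterministic lexicographic ties", {
  rel <- tibble::tibble(
    drug = c("D2", "D1", "D3", "D1"),
    disease = c("Z1", "Z2", "Z1", "Z1"),
    n_bridges = 1L, n_meaningful = 1L,
    baseline = c(5, 3, 9, 3), sum = 0, max = 0, hybrid = c(5, 3, 9, 3),
    best_bridge_gene = "G", best_bridge_sim = 0.9,
    bridges = list(tibble::tibble())
  )
  r <- rank_relations(rel, "baseline")
  expect_equal(r$score, c(9, 5, 3, 3))
  # ties broken by (drug, disease) ascending
  expect_equal(r$drug[3:4], c("D1", "D1"))
  expect_equal(r$disease[3:4], c("Z1", "Z2"))
  # ranking is stable under repetition
  expect_equal(rank_relations(r, "baseline")$drug, r$drug)
})
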