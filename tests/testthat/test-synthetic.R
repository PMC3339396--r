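test_that("configuration is validated", {
  expect_error(synthetic_config(n_coherent_chains = 30, n_decoy_chains = 0,
                                n_drugs = 10),
               "more chains")
  expect_error(synthetic_config(coherence = 1.5), "coherence")
  expect_error(synthetic_config(decoy_frequency_multiplier = 0.5),
               "multiplier")
  expect_error(synthetic_config(n_coherent_chains = 0, n_decoy_chains = 0),
               "at least one chain")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("a minimal world has one abstract per planted interaction", {
  w <- generate_world(synthetic_config(
    n_coherent_chains = 1, n_decoy_chains = 0,
    abstracts_per_interaction = 1, seed = 4
  ))
  expect_equal(nrow(w$corpus), 2)
  expect_equal(nrow(w$gold), 1)
  expect_equal(nrow(truth_manifest(w)), 1)
})

test_that("same seed gives byte-identical world files", {
  cfg <- synthetic_config(n_coherent_chains = 3, n_decoy_chains = 3, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_world(cfg, dir = d1)
  generate_world(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("manifest covers every chain and contains the gold pairs", {
  cfg <- synthetic_config(n_coherent_chains = 2, n_decoy_chains = 3, seed = 9)
  w <- generate_world(cfg)
  m <- truth_manifest(w)
  expect_equal(nrow(m), 5)
  expect_equal(sum(m$type == "coherent"), 2)
  gold_keys <- w$gold$pair_key
  manifest_keys <- canonical_pair(m$drug, m$disease)
  expect_true(all(gold_keys %in% manifest_keys))
  # decoy signatures are disjoint between the two interactions
  dec <- m[m$type == "decoy", ]
  for (i in seq_len(nrow(dec))) {
    expect_length(intersect(strsplit(dec$context_ab[i], ",")[[1]],
                            strsplit(dec$context_bc[i], ",")[[1]]), 0)
  }
})

test_that("the pipeline recovers every planted interaction frequency", {
  w <- generate_world(synthetic_config(n_coherent_chains = 3,
                                       n_decoy_chains = 2, seed = 21))
  ints <- extract_interactions(tag_corpus(w$corpus, w$interaction_dict))
  m <- truth_manifest(w)
  ab <- dplyr::inner_join(m, ints, by = c(drug = "acc1", gene = "acc2"))
  bc <- dplyr::inner_join(m, ints, by = c(gene = "acc1", disease = "acc2"))
  expect_equal(nrow(ab), nrow(m))
  expect_equal(nrow(bc), nrow(m))
  expect_equal(ab$frequency, ab$freq_ab)
  expect_equal(bc$frequency, bc$freq_bc)
  # and nothing beyond the planted chains is extracted
  expect_equal(nrow(ints), 2 * nrow(m))
})

test_that("coherent chains beat decoys on context similarity in-world", {
  for (seed in 1:5) {
    w <- generate_world(synthetic_config(
      n_coherent_chains = 2, n_decoy_chains = 2, seed = 100 + seed
    ))
    mi <- tag_corpus(w$corpus, w$interaction_dict)
    mc <- tag_corpus(w$corpus, w$context_dict)
    ints <- extract_interactions(mi)
    cv <- build_context_vectors(ints, count_context_terms(mc))
    m <- truth_manifest(w)
    sims <- vapply(seq_len(nrow(m)), function(i) {
      context_similarity(cv,
                         paste(m$drug[i], m$gene[i], sep = "|"),
                         paste(m$gene[i], m$disease[i], sep = "|"),
                         "cosine")
    }, numeric(1))
    expect_gt(min(sims[m$type == "coherent"]),
              max(sims[m$type == "decoy"]))
  }
})

test_that("world corpus files round-trip through the corpus reader", {
  d <- withr::local_tempdir()
  w <- generate_world(synthetic_config(n_coherent_chains = 2,
                                       n_decoy_chains = 1, seed = 6), dir = d)
  corp <- read_corpus(w$paths$corpus, "jsonl")
  expect_equal(corp, w$corpus)
  dict <- read_dictionary(w$paths$interaction_dict, "interaction")
  expect_setequal(dict$accession, w$interaction_dict$accession)
  gold <- read_gold(w$paths$gold)
  expect_equal(gold$pair_key, w$gold$pair_key)
})
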