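test_that("make_lexicons realizes the requested overlap exactly", {
  base <- synth_config(source_lexicon_size = 40, target_lexicon_size = 40,
                       seed = 3)
  disjoint <- base; disjoint$lexicon_overlap <- 0
  lex <- make_lexicons(disjoint)
  expect_length(intersect(lex$source, lex$target), 0L)

  same <- base; same$lexicon_overlap <- 1
  lex <- make_lexicons(same)
  expect_setequal(lex$source, lex$target)

  half <- base; half$lexicon_overlap <- 0.5
  lex <- make_lexicons(half)
  expect_length(intersect(lex$source, lex$target), 20L)
  expect_length(unique(lex$source), 40L)
  expect_length(unique(lex$target), 40L)

  impossible <- base; impossible$lexicon_overlap <- 1
  impossible$source_lexicon_size <- 10L
  expect_error(make_lexicons(impossible), "only 10")
})

test_that("generation is deterministic and respects the empty case", {
  sc <- synth_config(n_sentences = 50, seed = 17)
  lex <- make_lexicons(sc)
  a <- generate_corpus(lex$target, sc, role = "t")
  b <- generate_corpus(lex$target, sc, role = "t")
  expect_identical(a, b)
  expect_length(generate_corpus(lex$target, sc, n_sentences = 0), 0L)
  dense <- synth_config(entity_density = 0.9, seed = 1)
  expect_error(generate_corpus(lex$target, dense), "infeasible")
})

test_that("realized entity density concentrates around the target", {
  sc <- synth_config(n_sentences = 5000, entity_density = 0.10, seed = 23)
  co <- generate_corpus(make_lexicons(sc)$target, sc, role = "d")
  expect_lt(abs(entity_word_density(co) - 0.10), 0.02)
})

test_that("noise-free corpora label every entity-pool token and nothing else", {
  sc <- synth_config(n_sentences = 300, seed = 5)
  co <- generate_corpus(make_lexicons(sc)$target, sc, role = "t")
  for (s in co$sentences) {
    expect_silent(parse_bio(s$labels, strict = TRUE))
    is_ent_word <- grepl("^ent", s$tokens)
    expect_equal(s$labels != "O", is_ent_word)
  }
})

test_that("corrupt_labels honors its rates and never corrupts structure", {
  sc <- synth_config(n_sentences = 200, seed = 7)
  co <- generate_corpus(make_lexicons(sc)$target, sc, role = "t")
  clean <- sc  # both rates zero
  expect_identical(corrupt_labels(co, clean), co)

  all_gone <- sc; all_gone$omission_rate <- 1
  gone <- corrupt_labels(co, all_gone)
  expect_equal(sum(unlist(ssner:::corpus_labels(gone)) != "O"), 0L)

  big <- synth_config(n_sentences = 6000, entity_density = 0.27, seed = 13)
  bigco <- generate_corpus(make_lexicons(big)$target, big, role = "t")
  n_ent <- sum(vapply(bigco$sentences,
                      function(s) nrow(parse_bio(s$labels)), integer(1)))
  expect_gt(n_ent, 10000)
  om <- big; om$omission_rate <- 0.3
  kept <- corrupt_labels(bigco, om)
  n_kept <- sum(vapply(kept$sentences,
                       function(s) nrow(parse_bio(s$labels)), integer(1)))
  expect_lt(abs((n_ent - n_kept) / n_ent - 0.3), 0.02)

  bd <- sc; bd$boundary_noise_rate <- 0.5
  shifted <- corrupt_labels(co, bd)
  for (i in seq_along(co$sentences)) {
    s0 <- co$sentences[[i]]; s1 <- shifted$sentences[[i]]
    expect_identical(s1$tokens, s0$tokens)
    expect_silent(parse_bio(s1$labels, strict = TRUE))
    sp0 <- parse_bio(s0$labels); sp1 <- parse_bio(s1$labels)
    expect_equal(nrow(sp1), nrow(sp0))
    expect_true(all(abs(sp1 - sp0) <= 1))  # at most one boundary by one token
  }
  expect_identical(corrupt_labels(co, bd), corrupt_labels(co, bd))
})

test_that("overlap_statistic counts unique case-folded entity strings", {
  mk <- function(tokens, labels, id) ner_sentence(tokens, labels, id = id)
  target <- ner_corpus(list(
    mk(c("A", "b"), c("B", "I"), "t1"),        # "a b"
    mk(c("c", "x"), c("B", "O"), "t2"),        # "c"
    mk(c("d", "a", "b"), c("B", "B", "I"), "t3")  # "d", "a b" again
  ))
  source <- ner_corpus(list(
    mk(c("a", "b", "e"), c("B", "I", "B"), "s1"),  # "a b", "e"
    mk(c("d"), "B", "s2")
  ))
  expect_equal(overlap_statistic(source, target), 2 / 3)
  expect_equal(overlap_statistic(target, target), 1)
  no_ent <- ner_corpus(list(mk(c("x"), "O", "n1")))
  expect_error(overlap_statistic(source, no_ent), "no labeled entities")

  sc <- synth_config(n_sentences = 150, lexicon_overlap = 0, seed = 2)
  lex <- make_lexicons(sc)
  src <- generate_corpus(lex$source, sc, role = "s", seed = 4)
  tgt <- generate_corpus(lex$target, sc, role = "t", seed = 5)
  expect_equal(overlap_statistic(src, tgt), 0)
})

test_that("overlap_statistic is monotone in the configured lexicon overlap", {
  stats <- vapply(c(0, 0.3, 0.6, 1), function(ov) {
    sc <- synth_config(n_sentences = 400, lexicon_overlap = ov,
                       source_lexicon_size = 60, target_lexicon_size = 60,
                       entity_density = 0.15, seed = 31)
    lex <- make_lexicons(sc)
    src <- generate_corpus(lex$source, sc, role = "s", seed = 32)
    tgt <- generate_corpus(lex$target, sc, role = "t", seed = 33)
    overlap_statistic(src, tgt)
  }, numeric(1))
  expect_true(all(diff(stats) >= 0))
  expect_lt(stats[1], 0.05)
  expect_gt(stats[4], 0.9)
})

test_that("synthetic word vectors encode a class signal", {
  sc <- synth_config(seed = 41)
  wv <- make_word_vectors(sc, embed_dim = 20, signal = 0.5)
  expect_identical(wv, make_word_vectors(sc, embed_dim = 20, signal = 0.5))
  is_ent <- grepl("^ent", rownames(wv))
  mu_e <- colMeans(wv[is_ent, ]); mu_b <- colMeans(wv[!is_ent, ])
  between <- sqrt(sum((mu_e - mu_b)^2))
  wv0 <- make_word_vectors(sc, embed_dim = 20, signal = 0)
  mu_e0 <- colMeans(wv0[is_ent, ]); mu_b0 <- colMeans(wv0[!is_ent, ])
  expect_gt(between, 3 * sqrt(sum((mu_e0 - mu_b0)^2)))

  f <- withr::local_tempfile()
  write_word2vec(wv, f)
  vocab <- structure(list(tokens = sort(rownames(wv))),
                     class = "ner_vocabulary")
  E <- load_word_vectors(f, vocab, embed_dim = 20, seed = 1)
  expect_equal(E[match(rownames(wv), vocab$tokens) + 1L, ],
               unname(wv), tolerance = 1e-12)
})

test_that("experiment bundles are deterministic end to end", {
  sc <- synth_config(n_sentences = 80, seed = 19)
  a <- make_experiment_data(sc, n_source = 80L, n_test = 30)
  b <- make_experiment_data(sc, n_source = 80L, n_test = 30)
  expect_identical(a, b)
  expect_true(ssner:::corpus_is_labeled(a$source))
  expect_gt(entity_word_density(a$source), entity_word_density(a$target))
})
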