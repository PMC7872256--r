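# Micro-scale experiment bundle shared by the workflow unit tests: tiny
# corpora and a tiny tagger so each training run takes well under a second.
micro_bundle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- synth_config(n_sentences = 60, background_vocab_size = 30,
                       entity_word_pool_size = 20, source_lexicon_size = 15,
                       target_lexicon_size = 15, entity_density = 0.15,
                       sentence_length_range = c(4L, 7L), seed = 77)
    data <- make_experiment_data(sc, n_source = 60L, n_test = 20,
                                 embed_dim = 8, embed_signal = 0.3)
    vocab <- build_vocabulary(data$source, data$target, data$test)
    emb <- ssner:::embedding_for_vocab(data$word_vectors, vocab, seed = 77)
    cache <<- list(data = data, vocab = vocab, emb = emb,
                   cfg = micro_config(seed = 1))
    cache
  }
})

test_that("selftrain_config validates the confidence threshold", {
  expect_error(selftrain_config(0), "0, 1")
  expect_error(selftrain_config(1 + 1e-9), "0, 1")
  expect_error(selftrain_config(0.5, max_iterations = 0), "at least 1")
  expect_equal(selftrain_config()$confidence_threshold, 0.9975)
})

test_that("pretrain and finetune validate their inputs", {
  b <- micro_bundle()
  small <- b$data$source[1:4]
  expect_error(pretrain(small, b$cfg, b$vocab), "at least 5")
  expect_error(finetune(NULL, small, b$cfg, b$vocab), "at least 5")
  expect_error(finetune(NULL, b$data$target[1:10], seed = 1),
               "config and vocab")
  unlab <- ner_corpus(lapply(1:6, function(i) {
    ner_sentence(c("a", "b"), id = paste0("u", i))
  }))
  expect_error(pretrain(unlab, b$cfg, b$vocab), "labeled")
})

test_that("an 80/20 fine-tuning split of 1000 sentences is 800/200", {
  sc <- synth_config(n_sentences = 1000, background_vocab_size = 50,
                     entity_word_pool_size = 30, source_lexicon_size = 20,
                     target_lexicon_size = 20, entity_density = 0.15,
                     sentence_length_range = c(3L, 5L), seed = 9)
  target <- generate_corpus(make_lexicons(sc)$target, sc, role = "t")
  vocab <- build_vocabulary(target)
  cfg <- micro_config(seed = 1, max_epochs = 1L)
  res <- finetune(NULL, target, cfg, vocab, seed = 5)
  expect_length(res$train, 800L)
  expect_length(res$val, 200L)
})

test_that("pretrain and finetune are seed-reproducible", {
  b <- micro_bundle()
  p1 <- pretrain(b$data$source, b$cfg, b$vocab, seed = 3, embeddings = b$emb)
  p2 <- pretrain(b$data$source, b$cfg, b$vocab, seed = 3, embeddings = b$emb)
  expect_identical(p1$params, p2$params)
  expect_identical(p1$history, p2$history)
  f1 <- finetune(p1, b$data$target, seed = 4)
  f2 <- finetune(p2, b$data$target, seed = 4)
  expect_identical(f1$tagger$params, f2$tagger$params)
})

test_that("self-training conserves ids, fixes validation, shrinks unsup", {
  b <- micro_bundle()
  labeled <- b$data$target[1:30]
  unsup <- b$data$target[31:60]
  st <- self_train(NULL, labeled, unsup, selftrain_config(0.3, 10),
                   config = b$cfg, vocab = b$vocab, seed = 2,
                   embeddings = b$emb)
  h <- st$history
  expect_true(all(h$n_moved >= 0))
  expect_true(all(diff(h$cumulative_pseudo_fraction) >= 0))
  # sentence-id conservation: train + val + remaining unsup = original ids
  moved_ids <- corpus_ids(st$train)
  val_ids <- corpus_ids(st$val)
  expect_length(intersect(moved_ids, val_ids), 0L)
  expect_true(all(c(moved_ids, val_ids) %in%
                  c(corpus_ids(labeled), corpus_ids(unsup))))
  # validation ids equal the initial 80/20 split and carry gold labels only
  parts <- split_corpus(labeled, c(0.8, 0.2), seed = 2)
  expect_identical(val_ids, corpus_ids(parts[[2]]))
  expect_true(all(vapply(st$val$sentences,
                         function(s) s$label_source == "gold", logical(1))))
  # moved sentences carry pseudo labels
  pseudo <- setdiff(moved_ids, corpus_ids(parts[[1]]))
  src <- vapply(st$train$sentences, function(s) s$label_source, character(1))
  expect_true(all(src[match(pseudo, moved_ids)] == "pseudo"))
  # labeled/unsup id collision is rejected
  expect_error(self_train(NULL, labeled, labeled, selftrain_config(0.5),
                          config = b$cfg, vocab = b$vocab, seed = 1,
                          embeddings = b$emb),
               "share sentence ids")
})

test_that("threshold 1.0 reduces self-training to plain fine-tuning", {
  b <- micro_bundle()
  labeled <- b$data$target[1:25]
  unsup <- b$data$target[26:50]
  ft <- finetune(NULL, labeled, b$cfg, b$vocab, seed = 6,
                 embeddings = b$emb)
  st <- self_train(NULL, labeled, unsup, selftrain_config(1.0),
                   config = b$cfg, vocab = b$vocab, seed = 6,
                   embeddings = b$emb)
  expect_equal(nrow(st$history), 1L)
  expect_equal(st$history$n_moved, 0L)
  expect_identical(st$tagger$params, ft$tagger$params)
})

test_that("a tiny threshold moves the whole unsupervised set at once", {
  b <- micro_bundle()
  labeled <- b$data$target[1:25]
  unsup <- b$data$target[26:50]
  st <- self_train(NULL, labeled, unsup, selftrain_config(1e-12),
                   config = b$cfg, vocab = b$vocab, seed = 2,
                   embeddings = b$emb)
  moved_rows <- st$history[st$history$n_moved > 0, ]
  expect_equal(nrow(moved_rows), 1L)  # exactly one movement iteration
  expect_equal(moved_rows$n_moved, 25L)
  expect_equal(max(st$history$cumulative_pseudo_fraction), 1)
})

test_that("self-training histories are reproducible", {
  b <- micro_bundle()
  labeled <- b$data$target[1:30]
  unsup <- b$data$target[31:55]
  run <- function() {
    self_train(NULL, labeled, unsup, selftrain_config(0.5, 5),
               config = b$cfg, vocab = b$vocab, seed = 11,
               embeddings = b$emb)
  }
  a <- run(); bb <- run()
  expect_identical(a$history, bb$history)
  expect_identical(a$tagger$params, bb$tagger$params)
})

test_that("run_scenario emits one row per cell and a threshold sweep", {
  b <- micro_bundle()
  sc <- scenario_config(b$data$source, b$data$target, b$data$test,
                        labeled_sizes = 20L, use_pretrain = FALSE,
                        use_selftrain = FALSE, seeds = 1L,
                        tagger_cfg = b$cfg,
                        word_vectors = b$data$word_vectors)
  res <- run_scenario(sc)
  expect_equal(nrow(res), 1L)
  expect_false(res$pretrain); expect_false(res$selftrain)
  expect_true(all(c("exact_f1", "partial_f1", "correct") %in% names(res)))

  sw <- scenario_config(b$data$source, b$data$target, b$data$test,
                        labeled_sizes = 20L, use_pretrain = FALSE,
                        use_selftrain = TRUE, seeds = 1L,
                        tagger_cfg = b$cfg,
                        st_cfg = selftrain_config(max_iterations = 3),
                        word_vectors = b$data$word_vectors,
                        thresholds = c(0.3, 0.99))
  res2 <- run_scenario(sw)
  expect_equal(nrow(res2), 2L)
  expect_equal(res2$threshold, c(0.3, 0.99))
  expect_true(all(res2$n_iterations >= 1))
  hist <- attr(res2, "histories")
  expect_gte(length(hist), 2L)
  for (h in hist) expect_true(all(diff(h$cumulative_pseudo_fraction) >= 0))

  expect_error(scenario_config(b$data$source, b$data$target, b$data$test,
                               labeled_sizes = 1000L),
               "exceeds the target corpus")
})
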