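test_that("load_word_vectors copies file rows and seeds the rest", {
  f <- withr::local_tempfile()
  writeLines(c("2 3", "aa 0.1 0.2 0.3", "bb -1 0 1"), f)
  vocab <- build_vocabulary(ner_corpus(list(ner_sentence(c("aa", "bb")))))
  E <- load_word_vectors(f, vocab, embed_dim = 3, seed = 5)
  expect_equal(dim(E), c(3L, 3L))  # unknown row + 2 words
  expect_equal(E[match("aa", vocab$tokens) + 1L, ], c(0.1, 0.2, 0.3))
  expect_equal(E[match("bb", vocab$tokens) + 1L, ], c(-1, 0, 1))
  expect_identical(E, load_word_vectors(f, vocab, embed_dim = 3, seed = 5))

  # no overlap with the vocabulary: all rows from the seeded initializer
  vocab2 <- build_vocabulary(ner_corpus(list(ner_sentence(c("cc", "dd")))))
  E2 <- load_word_vectors(f, vocab2, embed_dim = 3, seed = 9)
  expect_identical(E2, load_word_vectors(f, vocab2, embed_dim = 3, seed = 9))
  expect_true(all(abs(E2) <= 0.25))

  expect_error(load_word_vectors(f, vocab, embed_dim = 4, seed = 1),
               "does not match")
  writeLines(c("aa 0.1 0.2 0.3", "bb 1 2"), f)
  expect_error(load_word_vectors(f, vocab, embed_dim = 3), "dimension 2")
})

test_that("initialization is seed-deterministic and respects dimensions", {
  vocab <- build_vocabulary(toy_corpus(10))
  cfg <- micro_config(seed = 4)
  a <- init_tagger(cfg, vocab)
  b <- init_tagger(cfg, vocab)
  expect_identical(a$params, b$params)
  expect_equal(dim(a$params$W1f), c(8L, 24L))
  expect_equal(dim(a$params$W2f), c(12L, 24L))
  expect_equal(dim(a$params$trans), c(5L, 5L))
  expect_error(init_tagger(cfg, vocab, embeddings = matrix(0, 2, 8)),
               "must be a")
})

test_that("analytic gradients match directional finite differences", {
  vocab <- structure(list(tokens = c("a", "b", "c", "d", "e")),
                     class = "ner_vocabulary")
  cfg <- micro_config(seed = 11, freeze_embeddings = FALSE)
  tg <- init_tagger(cfg, vocab)
  tok <- list(c(2L, 3L, 4L), c(5L, 6L, 2L, 3L, 4L))
  lab <- list(c(0L, 1L, 2L), c(2L, 0L, 1L, 1L, 2L))
  loss_at <- function(p) {
    ssner:::tagger_loss_grad_cpp(p, tok, lab, cfg$recurrent_layers, FALSE)$loss
  }
  res <- ssner:::tagger_loss_grad_cpp(tg$params, tok, lab,
                                      cfg$recurrent_layers, FALSE)
  set.seed(2)
  for (r in 1:5) {
    dirs <- lapply(tg$params, function(m) {
      matrix(stats::rnorm(length(m)), nrow(m))
    })
    eps <- 1e-3
    plus <- tg$params; minus <- tg$params
    for (nm in names(dirs)) {
      plus[[nm]] <- plus[[nm]] + eps * dirs[[nm]]
      minus[[nm]] <- minus[[nm]] - eps * dirs[[nm]]
    }
    numeric_dd <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
    analytic_dd <- sum(vapply(names(dirs), function(nm) {
      sum(res$grads[[nm]] * dirs[[nm]])
    }, numeric(1)))
    expect_equal(analytic_dd, numeric_dd, tolerance = 5e-3)
  }
})

test_that("training is deterministic and leaves frozen embeddings untouched", {
  co <- toy_corpus(24, seed = 8)
  parts <- split_corpus(co, c(0.75, 0.25), seed = 2)
  vocab <- build_vocabulary(co)
  cfg <- micro_config(seed = 3)
  t1 <- fit_tagger(init_tagger(cfg, vocab), parts[[1]], parts[[2]])
  t2 <- fit_tagger(init_tagger(cfg, vocab), parts[[1]], parts[[2]])
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params$emb, init_tagger(cfg, vocab)$params$emb)
})

test_that("early stopping runs exactly 1 + patience epochs without improvement", {
  co <- toy_corpus(16, seed = 9)
  parts <- split_corpus(co, c(0.75, 0.25), seed = 2)
  vocab <- build_vocabulary(co)
  # zero learning rate: the validation score can never improve after epoch 1
  for (p in c(2L, 4L)) {
    cfg <- micro_config(seed = 3, learning_rate = 1e-12, max_epochs = 50L,
                        patience = p)
    tg <- fit_tagger(init_tagger(cfg, vocab), parts[[1]], parts[[2]])
    expect_equal(nrow(tg$history), 1L + p)
  }
})

test_that("training loss decreases on a single-sentence train set", {
  s <- ner_sentence(c("ent01", "w01", "ent02", "w02"), c("B", "O", "B", "O"))
  co <- ner_corpus(list(s))
  vocab <- build_vocabulary(co)
  cfg <- micro_config(seed = 5, learning_rate = 2e-2, max_epochs = 5L,
                      patience = 5L)
  tg <- fit_tagger(init_tagger(cfg, vocab), co, co)
  expect_true(all(diff(tg$history$loss) < 1e-6))
})

test_that("predict is deterministic, shape-safe and BIO-valid", {
  co <- toy_corpus(12, seed = 6)
  vocab <- build_vocabulary(co)
  tg <- init_tagger(micro_config(seed = 7), vocab)
  expect_length(predict(tg, ner_corpus(list()))$ids, 0L)
  p1 <- predict(tg, co)
  p2 <- predict(tg, co)
  expect_identical(p1, p2)
  for (i in seq_along(co$sentences)) {
    expect_length(p1$labels[[i]], length(co$sentences[[i]]$tokens))
    expect_silent(parse_bio(p1$labels[[i]]))  # lenient parse never errors
  }
  expect_true(all(p1$confidence > 0 & p1$confidence <= 1))
})

test_that("checkpoints round trip through save_tagger/load_tagger", {
  co <- toy_corpus(10)
  vocab <- build_vocabulary(co)
  tg <- init_tagger(micro_config(seed = 2), vocab)
  f <- withr::local_tempfile(fileext = ".rds")
  save_tagger(tg, f)
  back <- load_tagger(f)
  expect_identical(back$params, tg$params)
  expect_identical(predict(back, co), predict(tg, co))
})
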