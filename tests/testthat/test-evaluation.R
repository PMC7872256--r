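test_that("match_entities applies exact-then-partial one-to-one matching", {
  ct <- match_entities(rbind(c(0, 2), c(5, 6)), rbind(c(0, 2), c(5, 7)))
  expect_equal(unclass(ct)[c("correct", "partial", "missing", "spurious")],
               list(correct = 1L, partial = 1L, missing = 0L, spurious = 0L))
  ct0 <- match_entities(NULL, NULL)
  expect_equal(unlist(unclass(ct0)), c(correct = 0L, incorrect = 0L,
                                       partial = 0L, missing = 0L,
                                       spurious = 0L))
  ct2 <- match_entities(rbind(c(0, 3)), rbind(c(4, 5)))
  expect_equal(ct2$missing, 1L)
  expect_equal(ct2$spurious, 1L)
  expect_error(match_entities(rbind(c(0, 2), c(1, 3)), NULL), "overlap")
})

test_that("largest-overlap-first greedy pairing breaks ties to the left", {
  # one gold span overlapped by two predictions: the larger overlap wins
  ct <- match_entities(rbind(c(2, 6)), rbind(c(1, 3), c(3, 6)))
  expect_equal(ct$partial, 1L)
  expect_equal(ct$spurious, 1L)
  # equal overlaps: earlier predicted span is chosen; result is stable
  ct2 <- match_entities(rbind(c(2, 4)), rbind(c(1, 3), c(3, 5)))
  expect_equal(ct2$partial, 1L)
  expect_equal(ct2$spurious, 1L)
})

test_that("compute_metrics reproduces hand-worked precision/recall/F1", {
  rep <- compute_metrics(list(correct = 1, incorrect = 0, partial = 1,
                              missing = 0, spurious = 0))
  expect_equal(rep$exact_precision, 0.5)
  expect_equal(rep$exact_recall, 0.5)
  expect_equal(rep$exact_f1, 0.5)
  expect_equal(rep$partial_precision, 0.75)
  expect_equal(rep$partial_recall, 0.75)
  expect_equal(rep$partial_f1, 0.75)

  zero <- compute_metrics(list(correct = 0, incorrect = 0, partial = 0,
                               missing = 0, spurious = 0))
  expect_equal(unlist(zero[1:6]), setNames(rep(0, 6), names(unlist(zero[1:6]))))

  perfect <- compute_metrics(list(correct = 2, incorrect = 0, partial = 0,
                                  missing = 0, spurious = 0))
  expect_equal(perfect$exact_f1, 1)
  expect_equal(perfect$partial_f1, 1)
})

test_that("evaluate_corpus micro-aggregates counts across sentences", {
  g1 <- spans_to_bio(rbind(c(0, 2), c(5, 6)), 7)
  p1 <- spans_to_bio(rbind(c(0, 2), c(5, 7)), 7)
  g2 <- spans_to_bio(rbind(c(0, 3)), 6)
  p2 <- spans_to_bio(rbind(c(4, 5)), 6)
  gold <- ner_corpus(list(ner_sentence(letters[1:7], g1, id = "s1"),
                          ner_sentence(letters[1:6], g2, id = "s2")))
  pred <- ner_corpus(list(ner_sentence(letters[1:7], p1, id = "s1"),
                          ner_sentence(letters[1:6], p2, id = "s2")))
  rep <- evaluate_corpus(gold, pred)
  expect_equal(rep$counts$correct, 1L)
  expect_equal(rep$counts$partial, 1L)
  expect_equal(rep$counts$missing, 1L)
  expect_equal(rep$counts$spurious, 1L)
  expect_equal(rep$possible, 3)
  expect_equal(rep$actual, 3)
  expect_equal(rep$exact_f1, 1 / 3)

  # gold against itself is perfect everywhere
  self <- evaluate_corpus(gold, gold)
  expect_equal(self$exact_f1, 1)
  expect_equal(self$partial_f1, 1)

  # all-O predictions miss every gold entity
  allo <- ner_corpus(list(ner_sentence(letters[1:7], rep("O", 7), id = "s1"),
                          ner_sentence(letters[1:6], rep("O", 6), id = "s2")))
  rep0 <- evaluate_corpus(gold, allo)
  expect_equal(rep0$counts$missing, 3L)
  expect_equal(rep0$exact_f1, 0)
  expect_equal(rep0$partial_f1, 0)
})

test_that("evaluate_corpus validates alignment", {
  gold <- ner_corpus(list(ner_sentence(c("a", "b"), c("B", "O"), id = "s1")))
  bad_id <- ner_corpus(list(ner_sentence(c("a", "b"), c("B", "O"), id = "zz")))
  expect_error(evaluate_corpus(gold, bad_id), "s1")
  bad_len <- structure(list(ids = "s1", labels = list(c("B")),
                            confidence = NA_real_),
                       class = "ner_predictions")
  expect_error(evaluate_corpus(gold, bad_len), "length 1")
})

test_that("conservation, monotone credit and permutation invariance hold", {
  set.seed(99)
  for (r in 1:200) {
    n <- sample(3:14, 1)
    g <- parse_bio(random_bio(n))
    p <- parse_bio(random_bio(n))
    ct <- match_entities(g, p)
    expect_equal(ct$correct + ct$incorrect + ct$partial + ct$missing, nrow(g))
    expect_equal(ct$correct + ct$incorrect + ct$partial + ct$spurious, nrow(p))
    rep <- compute_metrics(ct)
    expect_gte(rep$partial_precision, rep$exact_precision)
    expect_gte(rep$partial_recall, rep$exact_recall)
    expect_gte(rep$partial_f1, rep$exact_f1)
  }
  set.seed(123)
  gold_s <- lapply(1:10, function(i) {
    n <- sample(4:10, 1)
    ner_sentence(sample(letters, n, TRUE), random_bio(n), id = paste0("s", i))
  })
  pred_lab <- lapply(gold_s, function(s) random_bio(length(s$tokens)))
  pred <- structure(list(ids = paste0("s", 1:10), labels = pred_lab,
                         confidence = rep(NA_real_, 10)),
                    class = "ner_predictions")
  full <- evaluate_corpus(ner_corpus(gold_s), pred)
  perm <- sample(10)
  shuffled <- evaluate_corpus(ner_corpus(gold_s[perm]), pred)
  expect_equal(full[1:8], shuffled[1:8])
})

test_that("exact-F1 agrees with an independent span-set implementation", {
  set.seed(55)
  for (r in 1:30) {
    gold_lab <- lapply(1:6, function(i) random_bio(sample(3:10, 1)))
    pred_lab <- lapply(gold_lab, function(g) random_bio(length(g)))
    gold <- ner_corpus(lapply(seq_along(gold_lab), function(i) {
      ner_sentence(rep("w", length(gold_lab[[i]])), gold_lab[[i]],
                   id = paste0("s", i))
    }))
    pred <- structure(list(ids = paste0("s", 1:6), labels = pred_lab,
                           confidence = rep(NA_real_, 6)),
                      class = "ner_predictions")
    expect_equal(evaluate_corpus(gold, pred)$exact_f1,
                 spanset_exact_f1(gold_lab, pred_lab))
  }
})
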