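# Shared builders for small fixtures and desk-scale experiment artifacts.

toy_corpus <- function(n = 20, len = 5, labeled = TRUE, name = "toy",
                       seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    sents <- lapply(seq_len(n), function(i) {
      m <- sample(seq(2, len + 2), 1)
      toks <- sample(c(sprintf("w%02d", 1:12), sprintf("ent%02d", 1:6)),
                     m, replace = TRUE)
      labels <- if (labeled) {
        ifelse(grepl("^ent", toks), "B", "O")
      } else NULL
      ner_sentence(toks, labels, id = sprintf("%s:%d", name, i))
    })
    ner_corpus(sents, name = name)
  })
}

micro_config <- function(seed = 1, ...) {
  defaults <- list(embed_dim = 8L, hidden_units = 6L, recurrent_layers = 2L,
                   batch_size = 8L, learning_rate = 5e-3, max_epochs = 5L,
                   patience = 3L, seed = seed)
  do.call(tagger_config, utils::modifyList(defaults, list(...)))
}

desk_config <- function(seed = 1, ...) {
  defaults <- list(embed_dim = 50L, hidden_units = 64L, batch_size = 32L,
                   learning_rate = 3e-3, max_epochs = 40L, patience = 10L,
                   seed = seed)
  do.call(tagger_config, utils::modifyList(defaults, list(...)))
}

# Desk-scale experiment bundle used by the acceptance checks; cached per
# (seed, target size) so that several test blocks can share one pre-trained
# checkpoint and one self-training run.
.acc_cache <- new.env(parent = emptyenv())

acc_bundle <- function(seed, n_target = 1500L, n_test = 400L) {
  key <- sprintf("bundle_%d_%d", seed, n_target)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  sc <- synth_config(n_sentences = n_target, seed = seed)
  data <- make_experiment_data(sc, n_test = n_test)
  vocab <- build_vocabulary(data$source, data$target, data$test)
  emb <- ssner:::embedding_for_vocab(data$word_vectors, vocab, seed = seed)
  b <- list(cfg = desk_config(seed), data = data, vocab = vocab, emb = emb)
  .acc_cache[[key]] <- b
  b
}

acc_pretrained <- function(seed, n_target = 1500L) {
  key <- sprintf("pre_%d_%d", seed, n_target)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  b <- acc_bundle(seed, n_target)
  ck <- pretrain(b$data$source, b$cfg, b$vocab, seed = seed + 100L,
                 embeddings = b$emb)
  .acc_cache[[key]] <- ck
  ck
}

acc_selftrain <- function(seed, size, threshold = 0.9975,
                          n_target = 1500L) {
  key <- sprintf("st_%d_%d_%s", seed, size, format(threshold))
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  b <- acc_bundle(seed, n_target)
  ck <- acc_pretrained(seed, n_target)
  sets <- ssner:::subsample_labeled(b$data$target, size, seed * 11L)
  res <- self_train(ck, sets$labeled, sets$unsup,
                    selftrain_config(threshold, max_iterations = 6L),
                    seed = seed)
  res$test_exact_f1 <- evaluate_corpus(b$data$test,
                                       predict(res$tagger, b$data$test))$exact_f1
  .acc_cache[[key]] <- res
  res
}

acc_finetune <- function(seed, size, use_pretrain = TRUE,
                         n_target = 1500L) {
  key <- sprintf("ft_%d_%d_%d_%d", seed, size, use_pretrain, n_target)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  b <- acc_bundle(seed, n_target)
  ck <- if (use_pretrain) acc_pretrained(seed, n_target) else NULL
  sets <- ssner:::subsample_labeled(b$data$target, size, seed * 11L)
  res <- finetune(ck, sets$labeled, config = b$cfg, vocab = b$vocab,
                  seed = seed, embeddings = b$emb)
  res$test_exact_f1 <- evaluate_corpus(b$data$test,
                                       predict(res$tagger, b$data$test))$exact_f1
  .acc_cache[[key]] <- res
  res
}
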