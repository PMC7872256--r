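#' Tagger hyperparameter configuration
#'
#' Defaults follow the reference setup for full-scale corpora: frozen 200-d
#' word embeddings, two bidirectional LSTM layers of 300 units per
#' direction, a linear-chain CRF output layer, Adam with batch size 128 and
#' learning rate 1e-4. `patience` is the number of consecutive epochs
#' without validation exact-F1 improvement tolerated before training stops
#' (5 is used for pre-training, 10 for fine-tuning). For desk-scale
#' experiments on small synthetic corpora a reduced tagger
#' (`embed_dim = 50`, `hidden_units = 64`, `learning_rate = 1e-3`) trains
#' in seconds; see the package vignette.
#'
#' @param embed_dim word embedding dimension.
#' @param hidden_units LSTM units per direction per layer.
#' @param recurrent_layers number of stacked bidirectional layers.
#' @param batch_size minibatch size for Adam.
#' @param learning_rate Adam step size.
#' @param max_epochs hard cap on training epochs.
#' @param patience early-stopping patience, in epochs.
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param freeze_embeddings if `TRUE` (default) the embedding table is not
#'   updated during training.
#' @param grad_clip global gradient-norm clipping threshold.
#' @return A `tagger_config` list.
#' @export
tagger_config <- function(embed_dim = 200L, hidden_units = 300L,
                          recurrent_layers = 2L, batch_size = 128L,
                          learning_rate = 1e-4, max_epochs = 200L,
                          patience = 10L, seed = 1L,
                          freeze_embeddings = TRUE, grad_clip = 5.0) {
  cfg <- list(embed_dim = as.integer(embed_dim),
              hidden_units = as.integer(hidden_units),
              recurrent_layers = as.integer(recurrent_layers),
              labels = BIO_LABELS,
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              seed = as.integer(seed),
              freeze_embeddings = isTRUE(freeze_embeddings),
              grad_clip = grad_clip)
  num <- c("embed_dim", "hidden_units", "recurrent_layers", "batch_size",
           "learning_rate", "max_epochs", "patience", "grad_clip")
  for (f in num) {
    if (cfg[[f]] <= 0) stop(sprintf("config field '%s' must be positive", f))
  }
  structure(cfg, class = "tagger_config")
}

#' Build a vocabulary from corpora
#'
#' Collects the unique tokens of one or more corpora. Index 1 is reserved
#' for the unknown token, so any out-of-vocabulary word maps to a valid
#' embedding row. For transfer-learning experiments the vocabulary should
#' be built from the union of the source (pre-training) and target corpora
#' so that one embedding table serves every stage.
#'
#' @param ... one or more [ner_corpus()] objects.
#' @return An object of class `ner_vocabulary`.
#' @export
build_vocabulary <- function(...) {
  corpora <- list(...)
  toks <- sort(unique(unlist(lapply(corpora, function(co) {
    unlist(corpus_tokens(co), use.names = FALSE)
  }))))
  structure(list(tokens = toks), class = "ner_vocabulary")
}

#' @export
print.ner_vocabulary <- function(x, ...) {
  cat(sprintf("<ner_vocabulary> %d tokens (+1 unknown slot)\n",
              length(x$tokens)))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens) + 1L  # + unknown row

token_indices <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  idx[is.na(idx)] <- 0L
  idx + 1L  # row 1 = unknown
}

#' Load word vectors in word2vec text format
#'
#' Reads a plain-text embedding file (`word v1 ... vd` per line, optional
#' `count dim` header line) and assembles the embedding table for a
#' vocabulary. Rows for words present in the file are copied verbatim;
#' rows for out-of-file words (and the unknown-token row) are drawn from a
#' seeded uniform(-0.25, 0.25) initializer, so the same file, vocabulary
#' and seed always give an identical table.
#'
#' @param path word2vec text file.
#' @param vocab an `ner_vocabulary`.
#' @param embed_dim expected embedding dimension; a file with a different
#'   dimension is an error.
#' @param seed seed for the out-of-vocabulary initializer.
#' @return Numeric matrix of `length(vocab$tokens) + 1` rows (row 1 is the
#'   unknown token) and `embed_dim` columns.
#' @export
load_word_vectors <- function(path, vocab, embed_dim, seed = 1L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) > 0) {
    head_parts <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
    if (length(head_parts) == 2 &&
        !anyNA(suppressWarnings(as.numeric(head_parts)))) {
      if (as.integer(head_parts[2]) != embed_dim) {
        stop(sprintf("word-vector file dimension %s does not match embed_dim %d",
                     head_parts[2], embed_dim))
      }
      lines <- lines[-1]
    }
  }
  E <- with_seed(seed, matrix(stats::runif(vocab_size(vocab) * embed_dim,
                                           -0.25, 0.25),
                              nrow = vocab_size(vocab)))
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) - 1L != embed_dim) {
      stop(sprintf("word-vector row for '%s' has dimension %d, expected %d",
                   parts[1], length(parts) - 1L, embed_dim))
    }
    row <- match(parts[1], vocab$tokens)
    if (!is.na(row)) E[row + 1L, ] <- as.numeric(parts[-1])
  }
  E
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nrow = nr)
}

#' Initialize a BiLSTM-CRF tagger
#'
#' Creates the full parameter set: the embedding table (either supplied,
#' e.g. from [load_word_vectors()], or drawn from the seeded
#' uniform(-0.25, 0.25) initializer), Glorot-initialized LSTM and
#' projection weights with forget-gate biases set to 1, and a zero CRF
#' transition matrix with virtual start/stop states. Initialization is
#' fully determined by `config$seed`.
#'
#' @param config a [tagger_config()].
#' @param vocab an `ner_vocabulary` from [build_vocabulary()].
#' @param embeddings optional pre-built embedding matrix
#'   (`length(vocab$tokens) + 1` rows, `config$embed_dim` columns).
#' @return An object of class `crf_tagger`.
#' @export
init_tagger <- function(config, vocab, embeddings = NULL) {
  D <- config$embed_dim; H <- config$hidden_units
  L <- length(config$labels)
  V <- vocab_size(vocab)
  if (!is.null(embeddings)) {
    if (!is.matrix(embeddings) || nrow(embeddings) != V ||
        ncol(embeddings) != D) {
      stop(sprintf("embeddings must be a %d x %d matrix", V, D))
    }
  }
  params <- with_seed(config$seed, {
    p <- list()
    p$emb <- if (is.null(embeddings)) {
      matrix(stats::runif(V * D, -0.25, 0.25), nrow = V)
    } else embeddings
    for (l in seq_len(config$recurrent_layers)) {
      in_dim <- if (l == 1) D else 2L * H
      for (d in c("f", "b")) {
        p[[sprintf("W%d%s", l, d)]] <- glorot(in_dim, 4L * H)
        p[[sprintf("U%d%s", l, d)]] <- glorot(H, 4L * H)
        bias <- matrix(0, 1, 4L * H)
        bias[1, (H + 1L):(2L * H)] <- 1  # forget-gate bias
        p[[sprintf("b%d%s", l, d)]] <- bias
      }
    }
    p$Wout <- glorot(2L * H, L)
    p$bout <- matrix(0, 1, L)
    p$trans <- matrix(0, L + 2L, L + 2L)
    p
  })
  structure(list(config = config, vocab = vocab, params = params,
                 history = NULL),
            class = "crf_tagger")
}

#' @export
print.crf_tagger <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<crf_tagger> %d-d embeddings (%s), %d x Bi-LSTM(%d), CRF; %s parameters\n",
              cfg$embed_dim,
              if (cfg$freeze_embeddings) "frozen" else "trainable",
              cfg$recurrent_layers, cfg$hidden_units,
              format(n_par, big.mark = ",")))
  if (!is.null(x$history)) {
    best <- which.max(x$history$val_exact_f1)
    cat(sprintf("  trained %d epochs; best val exact-F1 %.4f at epoch %d\n",
                nrow(x$history), x$history$val_exact_f1[best], best))
  }
  invisible(x)
}

corpus_token_ids <- function(vocab, corpus) {
  lapply(corpus_tokens(corpus), function(tk) token_indices(vocab, tk))
}

corpus_label_ids0 <- function(corpus) {
  lapply(corpus_labels(corpus), function(lb) match(lb, BIO_LABELS) - 1L)
}

adam_init <- function(params, skip) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in setdiff(names(params), skip)) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adam_step <- function(params, grads, state, lr, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  scale <- if (is.finite(clip) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a tagger with early stopping on validation exact-F1
#'
#' Minimizes the negative CRF sequence log-likelihood by Adam over seeded
#' shuffled minibatches. After every epoch the tagger is evaluated on the
#' validation corpus with entity-level exact-F1 ([evaluate_corpus()]);
#' training stops when the score has not improved for `patience`
#' consecutive epochs or when `max_epochs` is reached, and the weights of
#' the best-validation epoch are restored. With `freeze_embeddings` on
#' (the default) the embedding table is bit-identical before and after
#' training.
#'
#' @param tagger a `crf_tagger` (fresh from [init_tagger()] or previously
#'   trained, e.g. a pre-trained checkpoint).
#' @param train,val labeled [ner_corpus()] objects; both non-empty.
#' @param patience overrides `tagger$config$patience` when given.
#' @param seed overrides `tagger$config$seed` for batch shuffling when
#'   given (weight initialization happened in [init_tagger()]).
#' @param verbose print one line per epoch.
#' @return The trained `crf_tagger`; `$history` holds the epoch log
#'   (epoch, mean train loss, validation exact-F1).
#' @export
fit_tagger <- function(tagger, train, val, patience = NULL, seed = NULL,
                       verbose = FALSE) {
  cfg <- tagger$config
  if (length(train) == 0L || length(val) == 0L) {
    stop("train and validation corpora must be non-empty")
  }
  if (!corpus_is_labeled(train) || !corpus_is_labeled(val)) {
    stop("train and validation corpora must be fully labeled")
  }
  patience <- if (is.null(patience)) cfg$patience else as.integer(patience)
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)

  tok <- corpus_token_ids(tagger$vocab, train)
  lab <- corpus_label_ids0(train)
  val_tok <- corpus_token_ids(tagger$vocab, val)
  n <- length(tok)
  params <- tagger$params
  skip <- if (cfg$freeze_embeddings) "emb" else character(0)
  opt <- adam_init(params, skip)

  best_f1 <- -Inf
  best_params <- params
  bad_epochs <- 0L
  hist <- list()

  sent_len <- lengths(tok)
  with_seed(seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      # seeded shuffle, then stable length bucketing: batches stay random
      # but hold near-equal lengths, keeping padded compute low
      ord <- sample.int(n)
      ord <- ord[order(sent_len[ord])]
      starts <- seq(1L, n, by = cfg$batch_size)
      starts <- starts[sample.int(length(starts))]
      total_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        res <- tagger_loss_grad_cpp(params, tok[idx], lab[idx],
                                    cfg$recurrent_layers,
                                    cfg$freeze_embeddings)
        total_loss <- total_loss + res$loss * length(idx)
        upd <- adam_step(params, res$grads, opt, cfg$learning_rate,
                         cfg$grad_clip)
        params <- upd$params
        opt <- upd$state
      }
      val_pred <- predict_tokens(params, cfg, val_tok)
      val_f1 <- quick_exact_f1(corpus_labels(val), val_pred$labels)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  loss = total_loss / n,
                                  val_exact_f1 = val_f1)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  val exact-F1 %.4f",
                        epoch, total_loss / n, val_f1))
      }
      if (val_f1 > best_f1) {
        best_f1 <- val_f1
        best_params <- params
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= patience) break
      }
    }
  })
  tagger$params <- best_params
  tagger$history <- do.call(rbind, hist)
  tagger
}

# Decode token-id sequences with given parameters: Viterbi labels plus the
# geometric-mean path probability per sentence.
predict_tokens <- function(params, cfg, token_ids) {
  n <- length(token_ids)
  if (n == 0L) return(list(labels = list(), confidence = numeric(0)))
  labels <- vector("list", n)
  confidence <- numeric(n)
  ord <- order(lengths(token_ids))
  starts <- seq(1L, n, by = cfg$batch_size)
  for (s in starts) {
    idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
    ems <- tagger_forward_cpp(params, token_ids[idx], cfg$recurrent_layers)
    for (k in seq_along(idx)) {
      em <- ems[[k]]
      vit <- crf_viterbi_cpp(em, params$trans)
      logZ <- crf_logZ_cpp(em, params$trans)
      labels[[idx[k]]] <- BIO_LABELS[as.integer(vit$path) + 1L]
      confidence[idx[k]] <- exp((vit$score - logZ) / nrow(em))
    }
  }
  list(labels = labels, confidence = confidence)
}

# Exact-F1 without building corpus objects; used inside the training loop.
quick_exact_f1 <- function(gold_labels, pred_labels) {
  correct <- 0L; n_gold <- 0L; n_pred <- 0L
  for (i in seq_along(gold_labels)) {
    g <- parse_bio(gold_labels[[i]])
    p <- parse_bio(pred_labels[[i]])
    n_gold <- n_gold + nrow(g)
    n_pred <- n_pred + nrow(p)
    if (nrow(g) > 0 && nrow(p) > 0) {
      correct <- correct +
        sum(paste(g[, 1], g[, 2]) %in% paste(p[, 1], p[, 2]))
    }
  }
  if (correct == 0L) return(0)
  prec <- correct / n_pred
  rec <- correct / n_gold
  2 * prec * rec / (prec + rec)
}

#' Predict BIO labels and confidences for sentences
#'
#' Runs the encoder and Viterbi decoding on each sentence and attaches the
#' per-sentence confidence: the exponential of the predicted path's
#' log-likelihood divided by sentence length (a per-word geometric-mean
#' probability in `(0, 1]`). Deterministic for fixed weights; any existing
#' labels on the input sentences are ignored.
#'
#' @param object a trained `crf_tagger`.
#' @param corpus an [ner_corpus()] (or list of sentences) to tag.
#' @param ... unused.
#' @return An `ner_predictions` object: `ids`, `labels` (list of BIO
#'   vectors) and `confidence` (numeric vector).
#' @export
predict.crf_tagger <- function(object, corpus, ...) {
  if (inherits(corpus, "ner_sentence")) corpus <- ner_corpus(list(corpus))
  if (is.list(corpus) && !inherits(corpus, "ner_corpus")) {
    corpus <- ner_corpus(corpus)
  }
  ids <- corpus_ids(corpus)
  res <- predict_tokens(object$params, object$config,
                        corpus_token_ids(object$vocab, corpus))
  structure(list(ids = ids, labels = res$labels,
                 confidence = res$confidence),
            class = "ner_predictions")
}

#' @export
print.ner_predictions <- function(x, ...) {
  cat(sprintf("<ner_predictions> %d sentences", length(x$ids)))
  if (length(x$confidence) > 0) {
    cat(sprintf("; confidence min/median/max %.4f/%.4f/%.4f",
                min(x$confidence), stats::median(x$confidence),
                max(x$confidence)))
  }
  cat("\n")
  invisible(x)
}

#' Attach predicted labels to a corpus
#'
#' @param predictions an `ner_predictions` object.
#' @param corpus the corpus the predictions were made on (matched by id).
#' @param label_source recorded provenance for the new labels.
#' @return A labeled `ner_corpus`.
#' @export
predictions_to_corpus <- function(predictions, corpus,
                                  label_source = "pseudo") {
  idx <- match(corpus_ids(corpus), predictions$ids)
  if (anyNA(idx)) stop("predictions are missing some corpus sentence ids")
  sents <- lapply(seq_along(corpus$sentences), function(i) {
    s <- corpus$sentences[[i]]
    ner_sentence(s$tokens, predictions$labels[[idx[i]]], id = s$id,
                 label_source = label_source)
  })
  ner_corpus(sents, name = corpus$name)
}

#' Save / load a tagger checkpoint
#'
#' A checkpoint is a single self-describing archive holding the named
#' parameter arrays together with the `tagger_config`, the vocabulary and
#' the training history, so a run can be resumed or inspected later.
#'
#' @param tagger a `crf_tagger`.
#' @param path file path for the checkpoint.
#' @return `save_tagger()`: `path` invisibly; `load_tagger()`: the
#'   restored `crf_tagger`.
#' @export
save_tagger <- function(tagger, path) {
  saveRDS(unclass(tagger), path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  obj <- readRDS(path)
  stopifnot(all(c("config", "vocab", "params") %in% names(obj)))
  structure(obj, class = "crf_tagger")
}
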