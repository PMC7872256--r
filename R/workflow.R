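sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

#' Self-training configuration
#'
#' @param confidence_threshold per-sentence confidence (geometric-mean path
#'   probability) a prediction must reach to be moved from the unsupervised
#'   set into the training set. Default 0.9975, i.e. 99.75% average
#'   confidence across the tokens of the sentence.
#' @param max_iterations safety cap on self-training iterations.
#' @param refreeze_pseudo_labels if `TRUE` (default) pseudo-labels are
#'   frozen when a sentence is moved; if `FALSE` they are re-predicted by
#'   the newest model each iteration (ablation only).
#' @return A `selftrain_config` list.
#' @export
selftrain_config <- function(confidence_threshold = 0.9975,
                             max_iterations = 20L,
                             refreeze_pseudo_labels = TRUE) {
  if (!is.numeric(confidence_threshold) || confidence_threshold <= 0 ||
      confidence_threshold > 1) {
    stop("confidence_threshold must lie in (0, 1]")
  }
  if (max_iterations < 1L) stop("max_iterations must be at least 1")
  structure(list(confidence_threshold = confidence_threshold,
                 max_iterations = as.integer(max_iterations),
                 refreeze_pseudo_labels = isTRUE(refreeze_pseudo_labels)),
            class = "selftrain_config")
}

#' Pre-train a tagger on a large annotated source corpus
#'
#' Splits the source corpus 80/20 into train/validation (seeded), trains a
#' freshly initialized tagger with early stopping at patience 5 on
#' validation exact-F1, and returns the resulting checkpoint. The
#' vocabulary should cover the target corpora too (build it with
#' [build_vocabulary()] over source and target) so the pre-trained
#' embedding rows are reused downstream.
#'
#' @param source_corpus fully labeled [ner_corpus()] (at least 5
#'   sentences).
#' @param config a [tagger_config()].
#' @param vocab an `ner_vocabulary`.
#' @param seed stage seed; defaults to `config$seed`.
#' @param embeddings optional embedding matrix (e.g. from
#'   [load_word_vectors()]).
#' @param patience early-stopping patience for pre-training.
#' @param verbose print per-epoch progress.
#' @return A trained `crf_tagger` checkpoint.
#' @export
pretrain <- function(source_corpus, config, vocab, seed = config$seed,
                     embeddings = NULL, patience = 5L, verbose = FALSE) {
  if (length(source_corpus) < 5L) {
    stop("source corpus must contain at least 5 sentences")
  }
  if (!corpus_is_labeled(source_corpus)) {
    stop("source corpus must be fully labeled")
  }
  parts <- split_corpus(source_corpus, c(0.8, 0.2), seed = seed)
  cfg <- config
  cfg$seed <- as.integer(seed)
  tagger <- init_tagger(cfg, vocab, embeddings = embeddings)
  fit_tagger(tagger, parts[[1]], parts[[2]], patience = patience,
             seed = seed, verbose = verbose)
}

#' Fine-tune on a small labeled target set
#'
#' Splits the labeled target sentences 80/20 into train/validation
#' (seeded; 1000 labeled sentences give exactly 800 train and 200
#' validation), initializes the model from the pre-trained checkpoint when
#' one is given and freshly otherwise, and trains with early stopping at
#' patience 10 on validation exact-F1.
#'
#' @param pretrained a `crf_tagger` checkpoint from [pretrain()], or
#'   `NULL` for training from scratch.
#' @param labeled_target fully gold-labeled [ner_corpus()] (at least 5
#'   sentences).
#' @param config,vocab required when `pretrained` is `NULL`; otherwise
#'   taken from the checkpoint.
#' @param seed stage seed controlling the split, any fresh
#'   initialization, and batch shuffling.
#' @param embeddings optional embedding matrix for fresh initialization.
#' @param patience early-stopping patience for fine-tuning.
#' @param verbose print per-epoch progress.
#' @return List with `tagger`, `train` and `val` (the split parts).
#' @export
finetune <- function(pretrained, labeled_target, config = NULL,
                     vocab = NULL, seed = 1L, patience = 10L,
                     embeddings = NULL, verbose = FALSE) {
  if (length(labeled_target) < 5L) {
    stop("fine-tuning requires at least 5 labeled sentences")
  }
  if (!corpus_is_labeled(labeled_target)) {
    stop("labeled target corpus must be fully labeled")
  }
  parts <- split_corpus(labeled_target, c(0.8, 0.2), seed = seed)
  tagger <- init_stage_tagger(pretrained, config, vocab, seed, embeddings)
  tagger <- fit_tagger(tagger, parts[[1]], parts[[2]], patience = patience,
                       seed = seed, verbose = verbose)
  list(tagger = tagger, train = parts[[1]], val = parts[[2]])
}

init_stage_tagger <- function(pretrained, config, vocab, seed,
                              embeddings = NULL) {
  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "crf_tagger"))
    tagger <- pretrained
    tagger$history <- NULL
    tagger
  } else {
    if (is.null(config) || is.null(vocab)) {
      stop("config and vocab are required when no pre-trained checkpoint is given")
    }
    cfg <- config
    cfg$seed <- as.integer(seed)
    init_tagger(cfg, vocab, embeddings = embeddings)
  }
}

#' Iterative confidence-thresholded self-training
#'
#' Implements the semi-supervised loop: (a) train a model on the current
#' training set, re-initializing each iteration from the pre-trained
#' checkpoint (or freshly when there is none) with a fresh optimizer;
#' (b) predict on the unsupervised set; (c) move every sentence whose
#' confidence reaches the threshold into the training set with its
#' pseudo-labels (`label_source = "pseudo"`); (d) stop when nothing moved,
#' the unsupervised set is exhausted, or `max_iterations` is reached. The
#' gold validation set fixed by the initial 80/20 split is retained
#' unchanged throughout, so validation only ever sees gold labels. When
#' sentences were moved in the last iteration a final training on the
#' enlarged set produces the returned model; the per-iteration history
#' lets callers select a best-validation model instead.
#'
#' @inheritParams finetune
#' @param unsup_corpus [ner_corpus()] of unlabeled sentences (any labels
#'   are ignored and stripped).
#' @param st_config a [selftrain_config()].
#' @param test_corpus optional labeled corpus evaluated every iteration
#'   for the history trace.
#' @return List with `tagger`, `history` (one row per training round:
#'   `iteration`, `n_moved`, `cumulative_pseudo_fraction`, validation and
#'   optional test metrics), `train`, `val`.
#' @export
self_train <- function(pretrained, labeled_target, unsup_corpus,
                       st_config = selftrain_config(), config = NULL,
                       vocab = NULL, seed = 1L, patience = 10L,
                       embeddings = NULL, test_corpus = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(st_config, "selftrain_config"))
  if (length(labeled_target) < 5L) {
    stop("self-training requires at least 5 labeled sentences")
  }
  overlap <- intersect(corpus_ids(labeled_target), corpus_ids(unsup_corpus))
  if (length(overlap) > 0) {
    stop("labeled and unsupervised sets share sentence ids: ", overlap[1])
  }
  # strip any labels from the unsupervised pool
  unsup <- ner_corpus(lapply(unsup_corpus$sentences, function(s) {
    ner_sentence(s$tokens, NULL, id = s$id)
  }), name = unsup_corpus$name)

  parts <- split_corpus(labeled_target, c(0.8, 0.2), seed = seed)
  gold_train <- parts[[1]]
  val <- parts[[2]]
  pseudo <- list()  # moved sentences, in move order
  n_pool <- length(gold_train) + length(unsup)

  history <- list()
  tagger <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    iter_seed <- sub_seed(seed, iter - 1L)
    if (iter == 1L) iter_seed <- as.integer(seed)  # round 1 == plain fine-tune
    train <- ner_corpus(c(gold_train$sentences, pseudo),
                        name = gold_train$name)
    tagger <- init_stage_tagger(pretrained, config, vocab, iter_seed,
                                embeddings)
    tagger <- fit_tagger(tagger, train, val, patience = patience,
                         seed = iter_seed, verbose = verbose)

    if (!st_config$refreeze_pseudo_labels && length(pseudo) > 0) {
      repred <- predict(tagger, ner_corpus(pseudo, name = "pseudo"))
      pseudo <- predictions_to_corpus(repred, ner_corpus(pseudo, name = "pseudo"),
                                      label_source = "pseudo")$sentences
    }

    n_moved <- 0L
    if (length(unsup) > 0) {
      preds <- predict(tagger, unsup)
      pass <- preds$confidence >= st_config$confidence_threshold
      n_moved <- sum(pass)
      if (n_moved > 0) {
        moved <- predictions_to_corpus(
          structure(list(ids = preds$ids[pass],
                         labels = preds$labels[pass],
                         confidence = preds$confidence[pass]),
                    class = "ner_predictions"),
          unsup[which(pass)], label_source = "pseudo")
        pseudo <- c(pseudo, moved$sentences)
        unsup <- unsup[which(!pass)]
      }
    }
    history[[iter]] <- selftrain_record(iter, n_moved,
                                        (length(gold_train) + length(pseudo)) / n_pool,
                                        tagger, val, test_corpus)
    if (verbose) {
      message(sprintf("self-train iteration %d: moved %d (unsup left %d)",
                      iter, n_moved, length(unsup)))
    }
    if (n_moved == 0L) break
    if (length(unsup) == 0L || iter >= st_config$max_iterations) {
      # last movement filled the train set; one final training round
      iter <- iter + 1L
      iter_seed <- sub_seed(seed, iter - 1L)
      train <- ner_corpus(c(gold_train$sentences, pseudo),
                          name = gold_train$name)
      tagger <- init_stage_tagger(pretrained, config, vocab, iter_seed,
                                  embeddings)
      tagger <- fit_tagger(tagger, train, val, patience = patience,
                           seed = iter_seed, verbose = verbose)
      history[[iter]] <- selftrain_record(iter, 0L,
                                          (length(gold_train) + length(pseudo)) / n_pool,
                                          tagger, val, test_corpus)
      break
    }
  }
  list(tagger = tagger, history = do.call(rbind, history),
       train = ner_corpus(c(gold_train$sentences, pseudo),
                          name = gold_train$name),
       val = val)
}

selftrain_record <- function(iter, n_moved, cum_frac, tagger, val,
                             test_corpus) {
  val_rep <- evaluate_corpus(val, predict(tagger, val))
  row <- data.frame(iteration = iter, n_moved = n_moved,
                    cumulative_pseudo_fraction = cum_frac,
                    val_exact_f1 = val_rep$exact_f1,
                    val_partial_f1 = val_rep$partial_f1)
  if (!is.null(test_corpus)) {
    test_rep <- evaluate_corpus(test_corpus, predict(tagger, test_corpus))
    row$test_exact_f1 <- test_rep$exact_f1
    row$test_partial_f1 <- test_rep$partial_f1
  }
  row
}

#' Scenario configuration for desk-scale experiments
#'
#' Describes a grid of low-resource experiments over a source corpus, a
#' target corpus and a held-out test corpus: for each labeled-set size,
#' seed, and arm (with/without pre-training, with/without self-training),
#' the labeled subset is drawn by a seeded permutation of the target
#' corpus, the remaining target sentences form the unsupervised set with
#' labels stripped, the stages are run and the final model is evaluated on
#' the test corpus.
#'
#' @param source,target,test [ner_corpus()] objects (source and target
#'   labeled).
#' @param labeled_sizes labeled-set sizes to sweep.
#' @param use_pretrain,use_selftrain if `TRUE` the corresponding dimension
#'   is swept over both arms (without and with); if `FALSE` only the
#'   "without" arm runs.
#' @param seeds integer seeds; each seed is one replicate.
#' @param tagger_cfg a [tagger_config()].
#' @param st_cfg a [selftrain_config()].
#' @param word_vectors optional named-row word-vector matrix (e.g. from
#'   [make_word_vectors()]) used to build the frozen embedding table for
#'   every arm.
#' @param thresholds optional numeric vector: threshold-sweep mode, which
#'   runs the pretrain+selftrain arm once per threshold.
#' @param fully_supervised also run an arm with the entire target corpus
#'   (train + unsupervised) gold-labeled.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(source, target, test,
                            labeled_sizes = c(250L, 500L, 1000L, 2000L),
                            use_pretrain = TRUE, use_selftrain = TRUE,
                            seeds = 1L,
                            tagger_cfg = tagger_config(),
                            st_cfg = selftrain_config(),
                            word_vectors = NULL,
                            thresholds = NULL,
                            fully_supervised = FALSE) {
  labeled_sizes <- as.integer(labeled_sizes)
  if (any(labeled_sizes <= 0L)) stop("labeled_sizes must be positive")
  if (any(labeled_sizes > length(target))) {
    stop(sprintf("labeled size %d exceeds the target corpus (%d sentences)",
                 max(labeled_sizes), length(target)))
  }
  structure(list(source = source, target = target, test = test,
                 labeled_sizes = labeled_sizes,
                 use_pretrain = isTRUE(use_pretrain),
                 use_selftrain = isTRUE(use_selftrain),
                 seeds = as.integer(seeds),
                 tagger_cfg = tagger_cfg, st_cfg = st_cfg,
                 word_vectors = word_vectors,
                 thresholds = thresholds,
                 fully_supervised = isTRUE(fully_supervised)),
            class = "scenario_config")
}

subsample_labeled <- function(target, size, seed) {
  perm <- with_seed(seed, sample.int(length(target)))
  labeled <- target[sort(perm[seq_len(size)])]
  rest_idx <- if (size < length(target)) sort(perm[(size + 1L):length(target)]) else integer(0)
  unsup <- ner_corpus(lapply(target$sentences[rest_idx], function(s) {
    ner_sentence(s$tokens, NULL, id = s$id)
  }), name = "unsup")
  list(labeled = labeled, unsup = unsup)
}

#' Run a scenario grid
#'
#' Executes every cell of the scenario and returns a long-format results
#' table: one row per labeled size x seed x arm (or per threshold in
#' threshold-sweep mode) with the six entity-level metrics on the test
#' corpus, the match counts, and the number of self-training rounds.
#' Per-run iteration histories are attached as the `"histories"`
#' attribute.
#'
#' @param scenario a [scenario_config()].
#' @param verbose print one line per completed run.
#' @return A `data.frame` of results.
#' @export
run_scenario <- function(scenario, verbose = FALSE) {
  stopifnot(inherits(scenario, "scenario_config"))
  vocab <- build_vocabulary(scenario$source, scenario$target, scenario$test)
  embeddings <- if (!is.null(scenario$word_vectors)) {
    embedding_for_vocab(scenario$word_vectors, vocab, seed = scenario$seeds[1])
  } else NULL
  rows <- list()
  histories <- list()
  sweep <- !is.null(scenario$thresholds)
  p_arms <- if (scenario$use_pretrain) c(FALSE, TRUE) else FALSE
  s_arms <- if (scenario$use_selftrain) c(FALSE, TRUE) else FALSE
  if (sweep) { p_arms <- scenario$use_pretrain; s_arms <- TRUE }

  for (seed in scenario$seeds) {
    pre <- NULL
    if (any(p_arms)) {
      pre <- pretrain(scenario$source, scenario$tagger_cfg, vocab,
                      seed = sub_seed(seed, 101L), embeddings = embeddings)
    }
    for (size in scenario$labeled_sizes) {
      sets <- subsample_labeled(scenario$target, size, sub_seed(seed, 202L))
      thresholds <- if (sweep) scenario$thresholds else NA_real_
      for (th in thresholds) {
        st_cfg <- scenario$st_cfg
        if (!is.na(th)) st_cfg$confidence_threshold <- th
        for (use_p in p_arms) {
          ck <- if (use_p) pre else NULL
          for (use_s in s_arms) {
            run <- run_arm(ck, sets, st_cfg, scenario, vocab, seed, use_s,
                           embeddings)
            rep <- evaluate_corpus(scenario$test,
                                   predict(run$tagger, scenario$test))
            row <- cbind(data.frame(labeled_size = size, seed = seed,
                                    pretrain = use_p, selftrain = use_s,
                                    threshold = if (use_s) st_cfg$confidence_threshold else NA_real_,
                                    n_iterations = run$n_iterations),
                         metric_row(rep))
            rows[[length(rows) + 1L]] <- row
            if (!is.null(run$history)) {
              histories[[sprintf("size%d_seed%d_p%d_s%d_t%s", size, seed,
                                 use_p, use_s, format(st_cfg$confidence_threshold))]] <-
                run$history
            }
            if (verbose) {
              message(sprintf("size %4d seed %d pretrain=%s selftrain=%s: test exact-F1 %.4f",
                              size, seed, use_p, use_s, rep$exact_f1))
            }
          }
        }
      }
    }
    if (scenario$fully_supervised) {
      ft <- finetune(NULL, scenario$target, scenario$tagger_cfg, vocab,
                     seed = sub_seed(seed, 303L), embeddings = embeddings)
      rep <- evaluate_corpus(scenario$test, predict(ft$tagger, scenario$test))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(labeled_size = length(scenario$target), seed = seed,
                         pretrain = FALSE, selftrain = FALSE,
                         threshold = NA_real_, n_iterations = 1L),
              metric_row(rep))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histories") <- histories
  out
}

run_arm <- function(checkpoint, sets, st_cfg, scenario, vocab, seed,
                    use_selftrain, embeddings = NULL) {
  if (use_selftrain) {
    res <- self_train(checkpoint, sets$labeled, sets$unsup, st_cfg,
                      config = scenario$tagger_cfg, vocab = vocab,
                      seed = sub_seed(seed, 404L), embeddings = embeddings)
    list(tagger = res$tagger, history = res$history,
         n_iterations = nrow(res$history))
  } else {
    res <- finetune(checkpoint, sets$labeled, config = scenario$tagger_cfg,
                    vocab = vocab, seed = sub_seed(seed, 404L),
                    embeddings = embeddings)
    list(tagger = res$tagger, history = NULL, n_iterations = 1L)
  }
}
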