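#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical skeleton of real biomedical NER
#' corpora while keeping the planted structure learnable: a Zipf-distributed
#' background vocabulary, multiword entities drawn from a lexicon built over
#' a reserved entity-word pool (disjoint from the background vocabulary, so
#' gold labels are unambiguous), a controllable fraction of entity words
#' among all words (real corpora span roughly 0.01-0.41), a controllable
#' overlap between source and target entity lexicons (real source/target
#' pairs span roughly 9%-68%), and optional silver-standard corruption
#' (entity omissions and one-token boundary shifts) standing in for
#' rule-based annotation noise.
#'
#' @param n_sentences number of sentences to generate.
#' @param background_vocab_size size of the non-entity vocabulary.
#' @param entity_word_pool_size size of the reserved entity-word pool from
#'   which lexicon entries are built.
#' @param source_lexicon_size,target_lexicon_size number of entity strings
#'   in the source / target lexicons.
#' @param lexicon_overlap fraction of the target lexicon also present in
#'   the source lexicon, in `[0, 1]`.
#' @param entity_density target fraction of entity words among all words,
#'   in `(0, 1)`; see [density_preset()] for values mirroring real corpora.
#' @param entity_length_weights sampling weights for entity lengths 1-3.
#' @param boundary_noise_rate,omission_rate silver-standard corruption
#'   rates in `[0, 1]`, applied per entity by [corrupt_labels()].
#' @param sentence_length_range integer range of background tokens per
#'   sentence (entities are inserted on top).
#' @param zipf_exponent exponent of the background word distribution.
#' @param seed integer seed; identical configurations generate
#'   byte-identical corpora.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sentences = 1000L,
                         background_vocab_size = 500L,
                         entity_word_pool_size = 400L,
                         source_lexicon_size = 300L,
                         target_lexicon_size = 300L,
                         lexicon_overlap = 0.3,
                         entity_density = 0.05,
                         entity_length_weights = c(0.55, 0.30, 0.15),
                         boundary_noise_rate = 0,
                         omission_rate = 0,
                         sentence_length_range = c(6L, 12L),
                         zipf_exponent = 1.1,
                         seed = 1L) {
  cfg <- list(n_sentences = as.integer(n_sentences),
              background_vocab_size = as.integer(background_vocab_size),
              entity_word_pool_size = as.integer(entity_word_pool_size),
              source_lexicon_size = as.integer(source_lexicon_size),
              target_lexicon_size = as.integer(target_lexicon_size),
              lexicon_overlap = lexicon_overlap,
              entity_density = entity_density,
              entity_length_weights = entity_length_weights / sum(entity_length_weights),
              boundary_noise_rate = boundary_noise_rate,
              omission_rate = omission_rate,
              sentence_length_range = as.integer(sentence_length_range),
              zipf_exponent = zipf_exponent,
              seed = as.integer(seed))
  if (cfg$lexicon_overlap < 0 || cfg$lexicon_overlap > 1) {
    stop("lexicon_overlap must lie in [0, 1]")
  }
  if (cfg$entity_density <= 0 || cfg$entity_density >= 1) {
    stop("entity_density must lie in (0, 1)")
  }
  if (any(c(cfg$boundary_noise_rate, cfg$omission_rate) < 0) ||
      any(c(cfg$boundary_noise_rate, cfg$omission_rate) > 1)) {
    stop("noise rates must lie in [0, 1]")
  }
  if (length(cfg$sentence_length_range) != 2L ||
      cfg$sentence_length_range[1] < 1L ||
      diff(cfg$sentence_length_range) < 0) {
    stop("sentence_length_range must be an increasing positive integer pair")
  }
  if (length(cfg$entity_length_weights) != 3L ||
      any(cfg$entity_length_weights < 0)) {
    stop("entity_length_weights must be three non-negative weights for lengths 1-3")
  }
  structure(cfg, class = "synth_config")
}

#' Entity-density presets mirroring real corpora
#'
#' `"benchmark-like"` (0.05) is typical of human-annotated benchmark NER
#' datasets, `"semmed-like"` (0.27) of a large rule-annotated silver
#' corpus, `"medmentions-like"` (0.41) of a densely annotated gold corpus.
#'
#' @param name one of `"benchmark-like"`, `"semmed-like"`,
#'   `"medmentions-like"`.
#' @return The entity-word density as a number.
#' @export
density_preset <- function(name = c("benchmark-like", "semmed-like",
                                    "medmentions-like")) {
  name <- match.arg(name)
  c("benchmark-like" = 0.05, "semmed-like" = 0.27,
    "medmentions-like" = 0.41)[[name]]
}

entity_pool <- function(config) {
  sprintf("ent%04d", seq_len(config$entity_word_pool_size))
}

sample_entity_strings <- function(n, pool, weights) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 100L) stop("entity pool too small to build unique lexicons")
    len <- sample.int(3L, n, replace = TRUE, prob = weights)
    batch <- vapply(len, function(m) {
      paste(sample(pool, m, replace = TRUE), collapse = " ")
    }, character(1))
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

#' Build source and target entity lexicons with controlled overlap
#'
#' Generates unique multiword entity strings from the reserved entity-word
#' pool. Exactly `round(lexicon_overlap * target_lexicon_size)` target
#' entries are also placed in the source lexicon; the remainder of each
#' lexicon is disjoint. Deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return List with character vectors `source` and `target`.
#' @export
make_lexicons <- function(config) {
  n_shared <- round(config$lexicon_overlap * config$target_lexicon_size)
  if (n_shared > config$source_lexicon_size) {
    stop(sprintf("overlap requires %d shared entries but the source lexicon has only %d",
                 n_shared, config$source_lexicon_size))
  }
  pool <- entity_pool(config)
  with_seed(config$seed, {
    total <- config$source_lexicon_size + config$target_lexicon_size - n_shared
    all_entries <- sample_entity_strings(total, pool,
                                         config$entity_length_weights)
    shared <- all_entries[seq_len(n_shared)]
    src_only <- all_entries[n_shared + seq_len(config$source_lexicon_size - n_shared)]
    tgt_only <- all_entries[config$source_lexicon_size +
                              seq_len(config$target_lexicon_size - n_shared)]
    list(source = c(shared, src_only), target = c(shared, tgt_only))
  })
}

#' Generate a synthetic BIO-annotated corpus
#'
#' Each sentence draws its background tokens Zipf-like from the background
#' vocabulary, then inserts entity mentions from the lexicon at distinct
#' positions (so two entities are always separated by at least one
#' background token and gold labels are unambiguous). The number of
#' insertions per sentence is Poisson with mean chosen so that the corpus
#' entity-word fraction matches `entity_density` in expectation.
#'
#' @param lexicon character vector of entity strings, e.g. one element of
#'   [make_lexicons()].
#' @param config a [synth_config()].
#' @param role corpus name, conventionally one of `"source"`, `"train"`,
#'   `"unsup"`, `"test"`; also the sentence-id prefix.
#' @param n_sentences number of sentences; defaults to
#'   `config$n_sentences`.
#' @param seed seed for this corpus; defaults to `config$seed`. Distinct
#'   roles should use distinct seeds.
#' @return A gold-labeled [ner_corpus()].
#' @export
generate_corpus <- function(lexicon, config, role = "synthetic",
                            n_sentences = config$n_sentences,
                            seed = config$seed) {
  if (length(lexicon) == 0L) stop("lexicon must be non-empty")
  lex_tokens <- strsplit(lexicon, " ", fixed = TRUE)
  mean_ent_len <- mean(lengths(lex_tokens))
  rng <- config$sentence_length_range
  mean_bg_len <- mean(rng)
  d <- config$entity_density
  lambda <- d / (1 - d) * mean_bg_len / mean_ent_len
  if (lambda > rng[1] + 1L) {
    stop(sprintf("entity_density %.3f is infeasible for sentence lengths %d-%d (needs %.2f insertions per sentence on average, at most %d slots)",
                 d, rng[1], rng[2], lambda, rng[1] + 1L))
  }
  bg_vocab <- sprintf("w%04d", seq_len(config$background_vocab_size))
  bg_prob <- seq_along(bg_vocab)^(-config$zipf_exponent)
  bg_prob <- bg_prob / sum(bg_prob)

  sentences <- with_seed(seed, {
    lapply(seq_len(n_sentences), function(i) {
      ell <- sample(rng[1]:rng[2], 1L)
      k <- min(stats::rpois(1L, lambda), ell + 1L)
      bg <- sample(bg_vocab, ell, replace = TRUE, prob = bg_prob)
      tokens <- bg
      labels <- rep("O", ell)
      if (k > 0L) {
        gaps <- sort(sample.int(ell + 1L, k) - 1L, decreasing = TRUE)
        ents <- sample.int(length(lexicon), k, replace = TRUE)
        for (j in seq_len(k)) {
          etoks <- lex_tokens[[ents[j]]]
          elabs <- c("B", rep("I", length(etoks) - 1L))
          at <- gaps[j]
          tokens <- append(tokens, etoks, after = at)
          labels <- append(labels, elabs, after = at)
        }
      }
      ner_sentence(tokens, labels, id = sprintf("%s:%d", role, i))
    })
  })
  ner_corpus(sentences, name = role)
}

#' Apply silver-standard label corruption
#'
#' Independently for each gold entity: with probability `omission_rate`
#' its labels are erased to `O`; otherwise with probability
#' `boundary_noise_rate` one of its boundaries shifts by one token, the
#' direction drawn uniformly among the shifts that keep the span non-empty,
#' inside the sentence, and non-overlapping with its neighbors. Tokens are
#' never modified, and the output always passes strict BIO validation.
#' Deterministic given `config$seed`.
#'
#' @param corpus a gold-labeled [ner_corpus()].
#' @param config a [synth_config()] supplying the two rates and the seed.
#' @return The corrupted `ner_corpus`.
#' @export
corrupt_labels <- function(corpus, config) {
  if (!corpus_is_labeled(corpus)) stop("corpus must be gold-labeled")
  om <- config$omission_rate
  bn <- config$boundary_noise_rate
  sentences <- with_seed(sub_seed(config$seed, 1L), {
    lapply(corpus$sentences, function(s) {
      spans <- parse_bio(s$labels, strict = TRUE)
      n <- length(s$tokens)
      if (nrow(spans) == 0L) return(s)
      keep <- stats::runif(nrow(spans)) >= om
      shift <- stats::runif(nrow(spans)) < bn
      new_spans <- list()
      prev_end <- 0L  # end of the previous surviving (possibly shifted) span
      for (r in seq_len(nrow(spans))) {
        if (!keep[r]) next
        st <- spans[r, 1]; en <- spans[r, 2]
        if (shift[r]) {
          next_start <- if (r < nrow(spans)) spans[r + 1L, 1] else n
          moves <- list()
          if (st - 1L >= prev_end) moves <- c(moves, list(c(st - 1L, en)))
          if (st + 1L < en) moves <- c(moves, list(c(st + 1L, en)))
          if (en + 1L <= next_start) moves <- c(moves, list(c(st, en + 1L)))
          if (en - 1L > st) moves <- c(moves, list(c(st, en - 1L)))
          if (length(moves) > 0L) {
            pick <- moves[[sample.int(length(moves), 1L)]]
            st <- pick[1]; en <- pick[2]
          }
        }
        new_spans <- c(new_spans, list(c(st, en)))
        prev_end <- en
      }
      mat <- if (length(new_spans) > 0L) do.call(rbind, new_spans) else NULL
      ner_sentence(s$tokens, spans_to_bio(mat, n), id = s$id,
                   label_source = s$label_source)
    })
  })
  ner_corpus(sentences, name = corpus$name)
}

gold_entity_strings <- function(corpus) {
  unlist(lapply(corpus$sentences, function(s) {
    spans <- parse_bio(s$labels)
    if (nrow(spans) == 0L) return(character(0))
    vapply(seq_len(nrow(spans)), function(r) {
      tolower(paste(s$tokens[(spans[r, 1] + 1L):spans[r, 2]], collapse = " "))
    }, character(1))
  }), use.names = FALSE)
}

#' Entity overlap between a target and a source corpus
#'
#' The fraction of unique target entity strings that also occur at least
#' once as a labeled entity in the source corpus. Entity strings are the
#' space-joined tokens of a gold span, case-folded.
#'
#' @param source_corpus,target_corpus labeled [ner_corpus()] objects.
#' @return A number in `[0, 1]`.
#' @export
overlap_statistic <- function(source_corpus, target_corpus) {
  tgt <- unique(gold_entity_strings(target_corpus))
  if (length(tgt) == 0L) stop("target corpus contains no labeled entities")
  src <- unique(gold_entity_strings(source_corpus))
  length(intersect(tgt, src)) / length(tgt)
}

#' Realized entity-word density of a labeled corpus
#'
#' @param corpus labeled [ner_corpus()].
#' @return Fraction of tokens labeled `B` or `I`.
#' @export
entity_word_density <- function(corpus) {
  labs <- unlist(corpus_labels(corpus), use.names = FALSE)
  mean(labs != "O")
}

#' Generate synthetic pre-trained word vectors
#'
#' Real biomedical word embeddings trained on PubMed-scale corpora place
#' entity-like words (genes, chemicals, diseases) in distinct regions of
#' the vector space, which is what makes a tagger over *frozen* embeddings
#' able to generalize from a few hundred labeled sentences. This function
#' produces the synthetic analogue: each word vector is a convex
#' combination of a class mean (one for the entity-word pool, one for the
#' background vocabulary) and a word-specific random direction,
#' `v_w = sqrt(signal) * mu_class + sqrt(1 - signal) * z_w`, at the scale
#' of the uniform(-0.25, 0.25) initializer. `signal` between 0 (pure
#' random, no distributional structure) and 1 (classes perfectly
#' separated) controls how much a model can lean on the embedding
#' geometry versus memorizing individual words.
#'
#' @param config a [synth_config()] (supplies the vocabularies and seed).
#' @param embed_dim embedding dimension.
#' @param signal fraction of embedding variance carried by the class
#'   mean, in `[0, 1]`.
#' @return Numeric matrix with one named row per word (background
#'   vocabulary and entity-word pool).
#' @export
make_word_vectors <- function(config, embed_dim = 50L, signal = 0.15) {
  if (signal < 0 || signal > 1) stop("signal must lie in [0, 1]")
  words <- c(sprintf("w%04d", seq_len(config$background_vocab_size)),
             entity_pool(config))
  is_ent <- c(rep(FALSE, config$background_vocab_size),
              rep(TRUE, config$entity_word_pool_size))
  scale <- 0.25 / sqrt(3)  # sd of uniform(-0.25, 0.25)
  with_seed(sub_seed(config$seed, 97L), {
    mu <- matrix(stats::rnorm(2L * embed_dim, sd = scale), nrow = 2L)
    z <- matrix(stats::rnorm(length(words) * embed_dim, sd = scale),
                nrow = length(words))
    wv <- sqrt(signal) * mu[is_ent + 1L, , drop = FALSE] +
      sqrt(1 - signal) * z
    rownames(wv) <- words
    wv
  })
}

#' Write word vectors in word2vec text format
#'
#' @param wv named-row matrix, e.g. from [make_word_vectors()].
#' @param path output file.
#' @param header write the `count dim` header line.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(wv, path, header = TRUE) {
  lines <- vapply(seq_len(nrow(wv)), function(i) {
    paste(rownames(wv)[i],
          paste(formatC(wv[i, ], format = "g", digits = 17), collapse = " "))
  }, character(1))
  if (header) lines <- c(paste(nrow(wv), ncol(wv)), lines)
  writeLines(lines, path)
  invisible(path)
}

# Assemble the embedding table for a vocabulary from a named word-vector
# matrix; rows absent from the matrix (and the unknown row) come from the
# seeded uniform(-0.25, 0.25) initializer.
embedding_for_vocab <- function(wv, vocab, seed = 1L) {
  embed_dim <- ncol(wv)
  E <- with_seed(seed, matrix(stats::runif(vocab_size(vocab) * embed_dim,
                                           -0.25, 0.25),
                              nrow = vocab_size(vocab)))
  hit <- match(vocab$tokens, rownames(wv))
  found <- which(!is.na(hit))
  E[found + 1L, ] <- wv[hit[found], , drop = FALSE]
  E
}

#' Generate a full source/target experiment bundle
#'
#' Convenience wrapper producing everything a transfer-learning experiment
#' needs: lexicons with the configured overlap, a (optionally corrupted)
#' source corpus, and gold target train/unsup/test corpora. Sub-seeds are
#' derived deterministically from `config$seed`.
#'
#' @param config a [synth_config()] describing the target corpus;
#'   `n_sentences` is the target train+unsup size.
#' @param source_config optional [synth_config()] for the source corpus;
#'   by default `config` with `n_source` sentences, density 0.27
#'   ("semmed-like") and silver noise (10% omissions, 5% boundary shifts).
#' @param n_source source corpus size when `source_config` is `NULL`.
#' @param n_test number of target test sentences.
#' @param embed_dim,embed_signal passed to [make_word_vectors()].
#' @return List with `source`, `target`, `test` corpora, the `lexicons`,
#'   and `word_vectors` (synthetic pre-trained embeddings).
#' @export
make_experiment_data <- function(config, source_config = NULL,
                                 n_source = 1000L, n_test = 500L,
                                 embed_dim = 50L, embed_signal = 0.15) {
  if (is.null(source_config)) {
    source_config <- config
    source_config$n_sentences <- as.integer(n_source)
    source_config$entity_density <- density_preset("semmed-like")
    source_config$omission_rate <- 0.10
    source_config$boundary_noise_rate <- 0.05
  }
  lex <- make_lexicons(config)
  source <- generate_corpus(lex$source, source_config, role = "source",
                            n_sentences = source_config$n_sentences,
                            seed = sub_seed(config$seed, 11L))
  if (source_config$omission_rate > 0 || source_config$boundary_noise_rate > 0) {
    source <- corrupt_labels(source, source_config)
  }
  target <- generate_corpus(lex$target, config, role = "target",
                            n_sentences = config$n_sentences,
                            seed = sub_seed(config$seed, 12L))
  test <- generate_corpus(lex$target, config, role = "test",
                          n_sentences = n_test,
                          seed = sub_seed(config$seed, 13L))
  list(source = source, target = target, test = test, lexicons = lex,
       word_vectors = make_word_vectors(config, embed_dim = embed_dim,
                                        signal = embed_signal))
}
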