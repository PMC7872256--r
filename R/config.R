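default_config_tree <- function() {
  list(
    seed = 1L,
    pretrain_patience = 5L,
    finetune_patience = 10L,
    split = list(train_fraction = 0.8),
    tagger = list(embed_dim = 200L, hidden_units = 300L,
                  recurrent_layers = 2L, batch_size = 128L,
                  learning_rate = 1e-4, max_epochs = 200L,
                  freeze_embeddings = TRUE, grad_clip = 5.0),
    selftrain = list(confidence_threshold = 0.9975, max_iterations = 20L,
                     refreeze_pseudo_labels = TRUE),
    synth = list(n_sentences = 1000L, background_vocab_size = 500L,
                 entity_word_pool_size = 400L, source_lexicon_size = 300L,
                 target_lexicon_size = 300L, lexicon_overlap = 0.3,
                 entity_density = 0.05,
                 entity_length_weights = c(0.55, 0.30, 0.15),
                 boundary_noise_rate = 0.0, omission_rate = 0.0,
                 sentence_length_range = c(6L, 12L), zipf_exponent = 1.1,
                 source_n_sentences = 1000L, source_entity_density = 0.27,
                 n_test = 500L, embed_signal = 0.15),
    scenario = list(labeled_sizes = c(250L, 500L, 1000L, 2000L),
                    use_pretrain = TRUE, use_selftrain = TRUE,
                    seeds = 1L, thresholds = NULL,
                    fully_supervised = FALSE)
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key '%s'", full))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        stop(sprintf("config key '%s' must be a mapping", full))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Parse and validate a run configuration
#'
#' Reads a YAML configuration file (or starts from an empty one), fills in
#' the package defaults — confidence threshold 0.9975, patience 5 for
#' pre-training and 10 for fine-tuning, batch size 128, learning rate
#' 1e-4, 80/20 train/validation splits — validates every field, and
#' rejects unknown keys by name. The returned tree carries constructed
#' [tagger_config()], [selftrain_config()] and [synth_config()] objects
#' ready for the workflow functions.
#'
#' @param path YAML file, or `NULL` for the pure defaults.
#' @param overrides named list merged on top of the file (used by the CLI
#'   for command-line flags).
#' @return A validated `ner_config` list.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  tree <- default_config_tree()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    tree <- merge_config(tree, user)
  }
  if (length(overrides) > 0) tree <- merge_config(tree, overrides)

  if (tree$split$train_fraction <= 0 || tree$split$train_fraction >= 1) {
    stop("config key 'split.train_fraction' must lie in (0, 1)")
  }
  if (tree$pretrain_patience < 1 || tree$finetune_patience < 1) {
    stop("patience values must be at least 1")
  }
  tagger_cfg <- do.call(tagger_config,
                        c(tree$tagger, list(seed = tree$seed,
                                            patience = tree$finetune_patience)))
  st_cfg <- do.call(selftrain_config, tree$selftrain)
  synth_fields <- setdiff(names(tree$synth),
                          c("source_n_sentences", "source_entity_density",
                            "n_test", "embed_signal"))
  synth_cfg <- do.call(synth_config,
                       c(tree$synth[synth_fields], list(seed = tree$seed)))
  structure(list(tree = tree, seed = as.integer(tree$seed),
                 tagger = tagger_cfg, selftrain = st_cfg,
                 synth = synth_cfg,
                 pretrain_patience = as.integer(tree$pretrain_patience),
                 finetune_patience = as.integer(tree$finetune_patience)),
            class = "ner_config")
}

#' @export
print.ner_config <- function(x, ...) {
  cat("<ner_config>\n")
  cat(sprintf("  seed %d; threshold %.4f; patience %d/%d (pretrain/finetune)\n",
              x$seed, x$selftrain$confidence_threshold,
              x$pretrain_patience, x$finetune_patience))
  cat(sprintf("  tagger: %d-d emb, %d x BiLSTM(%d), batch %d, lr %g\n",
              x$tagger$embed_dim, x$tagger$recurrent_layers,
              x$tagger$hidden_units, x$tagger$batch_size,
              x$tagger$learning_rate))
  invisible(x)
}

write_manifest <- function(out_dir, command, args, config, artifacts,
                           summary = NULL) {
  manifest <- list(
    tool = "ssner",
    version = as.character(utils::packageVersion("ssner")),
    command = command,
    args = args,
    seed = config$seed,
    config = config$tree,
    artifacts = artifacts,
    summary = summary,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
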