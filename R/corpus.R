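#' @useDynLib ssner, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

BIO_LABELS <- c("B", "I", "O")

#' Construct a tokenized sentence with optional BIO labels
#'
#' A sentence is the atomic unit of every corpus in this package: an ordered
#' vector of word tokens plus, optionally, one BIO tag per token. The
#' `label_source` field records whether labels are human annotations
#' (`"gold"`), model predictions kept by self-training (`"pseudo"`), or
#' absent (`"none"`).
#'
#' @param tokens character vector of word tokens; must be non-empty.
#' @param labels character vector of BIO tags (`"B"`, `"I"`, `"O"`), one per
#'   token, or `NULL` for an unlabeled sentence.
#' @param id opaque sentence identifier, unique within a corpus.
#' @param label_source one of `"gold"`, `"pseudo"`, `"none"`. Defaults to
#'   `"gold"` when labels are given and `"none"` otherwise.
#' @return An object of class `ner_sentence`.
#' @export
ner_sentence <- function(tokens, labels = NULL, id = "s1",
                         label_source = if (is.null(labels)) "none" else "gold") {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L) stop("a sentence must contain at least one token")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(tokens)) {
      stop(sprintf("sentence '%s': %d labels for %d tokens", id,
                   length(labels), length(tokens)))
    }
    bad <- setdiff(unique(labels), BIO_LABELS)
    if (length(bad) > 0L) {
      stop(sprintf("sentence '%s': invalid BIO label(s): %s", id,
                   paste(bad, collapse = ", ")))
    }
  }
  label_source <- match.arg(label_source, c("gold", "pseudo", "none"))
  if (is.null(labels) && label_source != "none") {
    stop("label_source must be 'none' for an unlabeled sentence")
  }
  structure(list(id = as.character(id), tokens = tokens, labels = labels,
                 label_source = label_source),
            class = "ner_sentence")
}

#' @export
print.ner_sentence <- function(x, ...) {
  cat(sprintf("<ner_sentence %s> %d tokens (%s)\n", x$id, length(x$tokens),
              x$label_source))
  if (is.null(x$labels)) {
    cat(" ", paste(x$tokens, collapse = " "), "\n")
  } else {
    cat(" ", paste(sprintf("%s/%s", x$tokens, x$labels), collapse = " "), "\n")
  }
  invisible(x)
}

#' Construct a corpus of sentences
#'
#' @param sentences list of [ner_sentence()] objects.
#' @param name corpus name; also the prefix of auto-generated sentence ids.
#' @return An object of class `ner_corpus`.
#' @export
ner_corpus <- function(sentences = list(), name = "corpus") {
  stopifnot(is.list(sentences))
  ids <- vapply(sentences, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sentence ids in corpus '%s': %s", name,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(sentences = sentences, name = name), class = "ner_corpus")
}

#' @export
length.ner_corpus <- function(x) length(x$sentences)

#' @export
`[.ner_corpus` <- function(x, i) {
  ner_corpus(x$sentences[i], name = x$name)
}

#' @export
print.ner_corpus <- function(x, ...) {
  ns <- length(x$sentences)
  ntok <- sum(vapply(x$sentences, function(s) length(s$tokens), integer(1)))
  src <- table(vapply(x$sentences, function(s) s$label_source, character(1)))
  cat(sprintf("<ner_corpus '%s'> %d sentences, %d tokens\n", x$name, ns, ntok))
  if (ns > 0) {
    cat("  label sources:",
        paste(sprintf("%s=%d", names(src), as.integer(src)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Sentence ids of a corpus
#'
#' @param corpus an [ner_corpus()].
#' @return Character vector of sentence ids, in corpus order.
#' @export
corpus_ids <- function(corpus) {
  vapply(corpus$sentences, function(s) s$id, character(1))
}

corpus_tokens <- function(corpus) {
  lapply(corpus$sentences, function(s) s$tokens)
}

corpus_labels <- function(corpus) {
  lapply(corpus$sentences, function(s) s$labels)
}

corpus_is_labeled <- function(corpus) {
  all(vapply(corpus$sentences, function(s) !is.null(s$labels), logical(1)))
}

#' Read a CoNLL-style BIO corpus
#'
#' Reads token-per-line text. Blank lines delimit sentences; each non-blank
#' line is either `token<TAB>label` (labeled dialect) or a bare `token`
#' (unlabeled dialect). The two dialects may not be mixed within one
#' sentence. Labels must be `B`, `I` or `O`; entity-type suffixes are not
#' accepted and must be mapped to plain BIO beforehand. Sentence ids are
#' generated as `<name>:<index>`.
#'
#' @param path path to the file.
#' @param name corpus name; defaults to the file name without extension.
#' @return An [ner_corpus()].
#' @seealso [write_conll()]
#' @export
read_conll <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  sentences <- list()
  tok_buf <- character(0)
  lab_buf <- character(0)
  start_line <- NA_integer_
  labeled <- NA
  flush <- function() {
    if (length(tok_buf) == 0L) return()
    idx <- length(sentences) + 1L
    labs <- if (isTRUE(labeled)) lab_buf else NULL
    sentences[[idx]] <<- ner_sentence(tok_buf, labs,
                                      id = sprintf("%s:%d", name, idx))
    tok_buf <<- character(0); lab_buf <<- character(0)
    labeled <<- NA; start_line <<- NA_integer_
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) { flush(); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    has_label <- length(parts) >= 2L
    if (length(parts) > 2L) {
      stop(sprintf("%s line %d: expected 'token' or 'token<TAB>label', got %d fields",
                   path, ln, length(parts)))
    }
    if (is.na(labeled)) {
      labeled <- has_label
      start_line <- ln
    } else if (labeled != has_label) {
      stop(sprintf("%s line %d: mixed labeled and unlabeled lines within the sentence starting at line %d",
                   path, ln, start_line))
    }
    if (has_label && !parts[2] %in% BIO_LABELS) {
      stop(sprintf("%s line %d: label '%s' is not one of B, I, O",
                   path, ln, parts[2]))
    }
    tok_buf <- c(tok_buf, parts[1])
    if (has_label) lab_buf <- c(lab_buf, parts[2])
  }
  flush()
  ner_corpus(sentences, name = name)
}

#' Write a corpus in CoNLL-style BIO format
#'
#' Inverse of [read_conll()]: one token per line, tab-separated label column
#' when the corpus is labeled, blank line after each sentence. The corpus
#' must be uniformly labeled or uniformly unlabeled.
#'
#' @param corpus an [ner_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path) {
  has_lab <- vapply(corpus$sentences, function(s) !is.null(s$labels), logical(1))
  if (length(has_lab) > 0 && !(all(has_lab) || !any(has_lab))) {
    stop("corpus mixes labeled and unlabeled sentences; write_conll requires a uniform corpus")
  }
  blocks <- vapply(corpus$sentences, function(s) {
    if (is.null(s$labels)) paste0(paste(s$tokens, collapse = "\n"), "\n")
    else paste0(paste(s$tokens, s$labels, sep = "\t", collapse = "\n"), "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n"), path, sep = "")
  invisible(path)
}

#' Parse a BIO label sequence into entity spans
#'
#' Converts per-token BIO tags into half-open, 0-based token intervals
#' `[start, end)`. A maximal run starting with `B` and continued by `I`
#' tags is one entity. In the default lenient mode an `I` with no live
#' entity (sequence-initial or following `O`) opens a new span, which is the
#' safe reading for model-produced tags; strict mode raises instead, which
#' is the right check for human annotations.
#'
#' @param labels character vector of `"B"`, `"I"`, `"O"`.
#' @param strict if `TRUE`, an orphan `I` is an error naming its position.
#' @return Integer matrix with columns `start` and `end`, one row per
#'   entity, ordered by position.
#' @examples
#' parse_bio(c("B", "I", "O", "B"))
#' @export
parse_bio <- function(labels, strict = FALSE) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), BIO_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid BIO label(s): %s", paste(bad, collapse = ", ")))
  }
  starts <- integer(0); ends <- integer(0)
  open <- FALSE
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    if (lab == "B" || (lab == "I" && !open)) {
      if (lab == "I" && strict) {
        stop(sprintf("orphan I at position %d (0-based index %d)", i, i - 1L))
      }
      starts <- c(starts, i - 1L); ends <- c(ends, i)
      open <- TRUE
    } else if (lab == "I") {
      ends[length(ends)] <- i
    } else {
      open <- FALSE
    }
  }
  cbind(start = starts, end = ends)
}

#' Convert entity spans to a BIO label sequence
#'
#' Inverse of [parse_bio()]. Adjacent spans are encoded unambiguously: the
#' second span starts with its own `B`.
#'
#' @param spans integer matrix with columns `start`, `end` (0-based,
#'   half-open); spans must be pairwise non-overlapping and within `[0, n)`.
#' @param n sentence length in tokens.
#' @return Character vector of `n` BIO tags.
#' @export
spans_to_bio <- function(spans, n) {
  spans <- as_span_matrix(spans)
  validate_spans(spans, n = n)
  labels <- rep("O", n)
  if (nrow(spans) > 0) {
    for (r in seq_len(nrow(spans))) {
      s <- spans[r, 1]; e <- spans[r, 2]
      labels[s + 1L] <- "B"
      if (e - s > 1L) labels[(s + 2L):e] <- "I"
    }
  }
  labels
}

as_span_matrix <- function(spans) {
  if (is.null(spans) || (is.matrix(spans) && nrow(spans) == 0) ||
      length(spans) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  if (!is.matrix(spans)) spans <- matrix(as.integer(spans), ncol = 2, byrow = TRUE)
  storage.mode(spans) <- "integer"
  colnames(spans) <- c("start", "end")
  spans
}

validate_spans <- function(spans, n = NULL, what = "spans") {
  if (nrow(spans) == 0) return(invisible(spans))
  if (any(spans[, 1] < 0) || any(spans[, 2] <= spans[, 1])) {
    stop(sprintf("%s must satisfy 0 <= start < end", what))
  }
  if (!is.null(n) && any(spans[, 2] > n)) {
    stop(sprintf("%s exceed the sentence length %d", what, n))
  }
  ord <- order(spans[, 1], spans[, 2])
  s <- spans[ord, , drop = FALSE]
  if (nrow(s) > 1 && any(s[-1, 1] < s[-nrow(s), 2])) {
    stop(sprintf("%s overlap", what))
  }
  invisible(spans)
}

#' Split a corpus into seeded random parts
#'
#' Partitions the sentences into parts whose sizes are the largest-remainder
#' rounding of `fractions * length(corpus)` (remainder ties broken toward
#' the earlier fraction). Membership is a seeded uniform permutation, so a
#' given seed always reproduces the same split.
#'
#' @param corpus an [ner_corpus()]; must be non-empty.
#' @param fractions non-negative numeric vector summing to 1, length >= 1.
#' @param seed integer seed controlling the permutation.
#' @return List of `ner_corpus` parts, in the order of `fractions`.
#' @export
split_corpus <- function(corpus, fractions, seed) {
  n <- length(corpus)
  if (n == 0L) stop("cannot split an empty corpus")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop(sprintf("fractions must sum to 1 (got %.12f)", sum(fractions)))
  }
  if (any(fractions < 0)) stop("fractions must be non-negative")
  sizes <- largest_remainder_sizes(fractions, n)
  perm <- with_seed(seed, sample.int(n))
  out <- vector("list", length(fractions))
  offset <- 0L
  for (k in seq_along(sizes)) {
    idx <- if (sizes[k] > 0) perm[(offset + 1L):(offset + sizes[k])] else integer(0)
    out[[k]] <- ner_corpus(corpus$sentences[sort(idx)], name = corpus$name)
    offset <- offset + sizes[k]
  }
  out
}

largest_remainder_sizes <- function(fractions, n) {
  raw <- fractions * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_part <- raw - sizes
    take <- order(-frac_part, seq_along(fractions))[seq_len(rem)]
    sizes[take] <- sizes[take] + 1L
  }
  as.integer(sizes)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
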