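#' Linear-chain CRF primitives
#'
#' These functions expose the tagger's CRF layer on plain matrices so that
#' its probabilistic semantics can be inspected (and tested) independently of
#' the neural encoder. An instance is described by an `n x L` emission score
#' matrix (one row per token, one column per label) and an
#' `(L+2) x (L+2)` transition matrix whose last two rows/columns are the
#' virtual start and stop states: `trans[L+1, j]` scores starting in label
#' `j` and `trans[j, L+2]` scores ending in label `j`. The score of a label
#' path is the sum of its emissions and transitions including the start and
#' stop bonuses; `crf_log_partition()` is the log-sum-exp of all `L^n` path
#' scores, computed by the forward recursion in log space.
#'
#' @param emissions numeric matrix, `n x L`, `n >= 1`.
#' @param transitions numeric matrix, `(L+2) x (L+2)`.
#' @return `crf_log_partition()`: the log partition function (a scalar).
#' @name crf_primitives
NULL

check_crf_args <- function(emissions, transitions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1L) {
    stop("emissions must be a matrix with at least one row")
  }
  L <- ncol(emissions)
  if (!is.matrix(transitions) || any(dim(transitions) != L + 2L)) {
    stop(sprintf("transitions must be a %d x %d matrix (labels + start/stop)",
                 L + 2L, L + 2L))
  }
  if (!all(is.finite(emissions)) || !all(is.finite(transitions))) {
    stop("emissions and transitions must be finite")
  }
  invisible(L)
}

#' @rdname crf_primitives
#' @export
crf_log_partition <- function(emissions, transitions) {
  check_crf_args(emissions, transitions)
  crf_logZ_cpp(emissions, transitions)
}

#' @rdname crf_primitives
#' @param labels either a character vector of BIO tags or an integer vector
#'   of 1-based label column indices, of length `n`.
#' @return `sequence_log_likelihood()`: the log-probability of `labels`
#'   under the CRF, i.e. path score minus log partition; always `<= 0`.
#' @export
sequence_log_likelihood <- function(emissions, transitions, labels) {
  L <- check_crf_args(emissions, transitions)
  y <- labels_to_index(labels, L, nrow(emissions))
  crf_score_cpp(emissions, transitions, y - 1L) -
    crf_logZ_cpp(emissions, transitions)
}

#' @rdname crf_primitives
#' @return `viterbi_decode()`: a list with `labels` (character BIO tags when
#'   `L == 3`, otherwise 1-based indices) and `score`, the unnormalized path
#'   score of the best path. Ties are broken toward the lower label index.
#' @export
viterbi_decode <- function(emissions, transitions) {
  L <- check_crf_args(emissions, transitions)
  res <- crf_viterbi_cpp(emissions, transitions)
  idx <- as.integer(res$path) + 1L
  labels <- if (L == length(BIO_LABELS)) BIO_LABELS[idx] else idx
  list(labels = labels, score = res$score)
}

#' @rdname crf_primitives
#' @param predicted_labels the Viterbi-decoded label sequence for this
#'   emission matrix (character BIO tags or 1-based indices).
#' @return `sentence_confidence()`: the per-word geometric-mean probability
#'   of the predicted path, `exp(log-likelihood / n)`, in `(0, 1]`. This is
#'   the quantity the self-training loop thresholds (default 0.9975).
#' @export
sentence_confidence <- function(emissions, transitions, predicted_labels) {
  ll <- sequence_log_likelihood(emissions, transitions, predicted_labels)
  exp(ll / nrow(emissions))
}

labels_to_index <- function(labels, L, n) {
  if (is.character(labels)) {
    if (L != length(BIO_LABELS)) {
      stop("character labels are only supported for the BIO label set")
    }
    y <- match(labels, BIO_LABELS)
    if (anyNA(y)) {
      stop(sprintf("invalid BIO label(s): %s",
                   paste(unique(labels[is.na(y)]), collapse = ", ")))
    }
  } else {
    y <- as.integer(labels)
    if (any(y < 1L) || any(y > L)) {
      stop(sprintf("label indices must lie in 1..%d", L))
    }
  }
  if (length(y) != n) {
    stop(sprintf("%d labels for %d emission rows", length(y), n))
  }
  y
}
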