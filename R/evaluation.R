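#' Match gold and predicted entity spans
#'
#' Entity-level accounting in the SemEval-2013 task 9.1 style, restricted
#' to untyped entities. Matching is one-to-one and runs in two passes:
#' first, identical spans are paired and counted *Correct*; second, the
#' remaining gold and predicted spans that overlap in at least one token
#' are paired greedily — largest overlap first, ties broken toward the
#' earlier (left-most) pair — and counted *Partial*. Unmatched gold spans
#' are *Missing*, unmatched predicted spans are *Spurious*. The
#' *Incorrect* category exists only for entity-type mismatches and is
#' always 0 here.
#'
#' @param gold_spans,pred_spans integer matrices with columns
#'   `start`, `end` (0-based, half-open), each sorted and pairwise
#'   disjoint within itself.
#' @return A `match_counts` list: `correct`, `incorrect`, `partial`,
#'   `missing`, `spurious`.
#' @examples
#' match_entities(rbind(c(0, 2), c(5, 6)), rbind(c(0, 2), c(5, 7)))
#' @export
match_entities <- function(gold_spans, pred_spans) {
  g <- as_span_matrix(gold_spans)
  p <- as_span_matrix(pred_spans)
  validate_spans(g, what = "gold spans")
  validate_spans(p, what = "predicted spans")

  g_open <- rep(TRUE, nrow(g))
  p_open <- rep(TRUE, nrow(p))
  correct <- 0L
  if (nrow(g) > 0 && nrow(p) > 0) {
    gkey <- paste(g[, 1], g[, 2])
    pkey <- paste(p[, 1], p[, 2])
    hit <- match(gkey, pkey)
    exact <- which(!is.na(hit))
    correct <- length(exact)
    g_open[exact] <- FALSE
    p_open[hit[exact]] <- FALSE
  }

  partial <- 0L
  gi <- which(g_open); pi <- which(p_open)
  if (length(gi) > 0 && length(pi) > 0) {
    cand <- expand.grid(g = gi, p = pi)
    ov <- pmin(g[cand$g, 2], p[cand$p, 2]) - pmax(g[cand$g, 1], p[cand$p, 1])
    keep <- ov > 0
    cand <- cand[keep, , drop = FALSE]
    ov <- ov[keep]
    if (nrow(cand) > 0) {
      ord <- order(-ov, g[cand$g, 1], p[cand$p, 1])
      for (k in ord) {
        if (g_open[cand$g[k]] && p_open[cand$p[k]]) {
          g_open[cand$g[k]] <- FALSE
          p_open[cand$p[k]] <- FALSE
          partial <- partial + 1L
        }
      }
    }
  }

  counts <- list(correct = correct, incorrect = 0L, partial = partial,
                 missing = sum(g_open), spurious = sum(p_open))
  structure(counts, class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("<match_counts> correct=%d incorrect=%d partial=%d missing=%d spurious=%d\n",
              x$correct, x$incorrect, x$partial, x$missing, x$spurious))
  invisible(x)
}

sum_match_counts <- function(counts_list) {
  out <- list(correct = 0L, incorrect = 0L, partial = 0L, missing = 0L,
              spurious = 0L)
  for (ct in counts_list) {
    for (f in names(out)) out[[f]] <- out[[f]] + ct[[f]]
  }
  structure(out, class = "match_counts")
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Compute exact and partial precision/recall/F1 from match counts
#'
#' Derives the six entity-level metrics from the Correct / Incorrect /
#' Partial / Missing / Spurious tallies:
#' `Possible = Correct + Incorrect + Partial + Missing` (the number of gold
#' entities), `Actual = Correct + Incorrect + Partial + Spurious` (the
#' number of predicted entities). Exact precision and recall are
#' `Correct / Actual` and `Correct / Possible`; the partial variants give
#' half credit for partial matches, `(Correct + 0.5 * Partial) / Actual`
#' and `(Correct + 0.5 * Partial) / Possible`. F1 is the harmonic mean;
#' every 0/0 ratio is defined as 0.
#'
#' @param counts a `match_counts` object from [match_entities()] (or any
#'   list with the five fields).
#' @return A `metric_report`: the six metrics plus `possible`, `actual`
#'   and the input `counts`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("correct", "incorrect", "partial", "missing", "spurious")
                %in% names(counts)))
  possible <- counts$correct + counts$incorrect + counts$partial + counts$missing
  actual <- counts$correct + counts$incorrect + counts$partial + counts$spurious
  ep <- safe_ratio(counts$correct, actual)
  er <- safe_ratio(counts$correct, possible)
  pp <- safe_ratio(counts$correct + 0.5 * counts$partial, actual)
  pr <- safe_ratio(counts$correct + 0.5 * counts$partial, possible)
  structure(list(exact_precision = ep, exact_recall = er,
                 exact_f1 = f1(ep, er),
                 partial_precision = pp, partial_recall = pr,
                 partial_f1 = f1(pp, pr),
                 possible = possible, actual = actual,
                 counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  cat(sprintf("  exact   P %.4f  R %.4f  F1 %.4f\n",
              x$exact_precision, x$exact_recall, x$exact_f1))
  cat(sprintf("  partial P %.4f  R %.4f  F1 %.4f\n",
              x$partial_precision, x$partial_recall, x$partial_f1))
  cat(sprintf("  counts: correct=%d partial=%d missing=%d spurious=%d (possible=%d actual=%d)\n",
              x$counts$correct, x$counts$partial, x$counts$missing,
              x$counts$spurious, x$possible, x$actual))
  invisible(x)
}

metric_row <- function(report) {
  data.frame(exact_precision = report$exact_precision,
             exact_recall = report$exact_recall,
             exact_f1 = report$exact_f1,
             partial_precision = report$partial_precision,
             partial_recall = report$partial_recall,
             partial_f1 = report$partial_f1,
             correct = report$counts$correct,
             incorrect = report$counts$incorrect,
             partial = report$counts$partial,
             missing = report$counts$missing,
             spurious = report$counts$spurious)
}

#' Evaluate predictions against a gold corpus
#'
#' Micro-aggregated entity-level evaluation: spans are matched sentence by
#' sentence (aligned by sentence id), the five match counts are summed over
#' the corpus, and the six metrics are computed once from the summed
#' counts. BIO parsing of predictions is lenient (an orphan `I` opens a
#' span), so arbitrary model output is scored without error.
#'
#' @param gold_corpus labeled [ner_corpus()].
#' @param predictions an `ner_predictions` object from
#'   [predict.crf_tagger()], or a labeled `ner_corpus` with matching ids.
#' @return A `metric_report`.
#' @export
evaluate_corpus <- function(gold_corpus, predictions) {
  if (!corpus_is_labeled(gold_corpus)) {
    stop("gold corpus must be fully labeled")
  }
  if (inherits(predictions, "ner_corpus")) {
    predictions <- structure(list(ids = corpus_ids(predictions),
                                  labels = corpus_labels(predictions),
                                  confidence = rep(NA_real_, length(predictions))),
                             class = "ner_predictions")
  }
  ids <- corpus_ids(gold_corpus)
  idx <- match(ids, predictions$ids)
  if (anyNA(idx)) {
    stop(sprintf("no prediction for sentence id '%s'", ids[which(is.na(idx))[1]]))
  }
  counts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- gold_corpus$sentences[[i]]
    plab <- predictions$labels[[idx[i]]]
    if (length(plab) != length(s$tokens)) {
      stop(sprintf("sentence '%s': prediction length %d does not match %d tokens",
                   s$id, length(plab), length(s$tokens)))
    }
    counts[[i]] <- match_entities(parse_bio(s$labels), parse_bio(plab))
  }
  total <- sum_match_counts(counts)
  n_gold <- sum(vapply(gold_corpus$sentences,
                       function(s) nrow(parse_bio(s$labels)), integer(1)))
  n_pred <- sum(vapply(seq_along(ids),
                       function(i) nrow(parse_bio(predictions$labels[[idx[i]]])),
                       integer(1)))
  stopifnot(total$correct + total$incorrect + total$partial + total$missing == n_gold,
            total$correct + total$incorrect + total$partial + total$spurious == n_pred)
  compute_metrics(total)
}
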