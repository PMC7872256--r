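# Brute-force CRF oracles: enumerate all L^n label paths.

enum_paths <- function(n, L) {
  as.matrix(expand.grid(rep(list(seq_len(L)), n)))
}

oracle_path_score <- function(em, tr, y) {
  n <- nrow(em); L <- ncol(em)
  s <- tr[L + 1, y[1]] + em[1, y[1]]
  if (n > 1) {
    for (t in 2:n) s <- s + tr[y[t - 1], y[t]] + em[t, y[t]]
  }
  s + tr[y[n], L + 2]
}

oracle_all_scores <- function(em, tr) {
  paths <- enum_paths(nrow(em), ncol(em))
  list(paths = paths,
       scores = apply(paths, 1, function(y) oracle_path_score(em, tr, y)))
}

oracle_logZ <- function(em, tr) {
  s <- oracle_all_scores(em, tr)$scores
  m <- max(s)
  m + log(sum(exp(s - m)))
}

random_crf_instance <- function(n, L = 3) {
  list(em = matrix(stats::rnorm(n * L), n, L),
       tr = matrix(stats::rnorm((L + 2)^2), L + 2, L + 2))
}

# Independent exact-F1 via span-set intersection, for cross-checking the
# matching-based evaluator.
spanset_exact_f1 <- function(gold_labels, pred_labels) {
  keyify <- function(labels, i) {
    sp <- parse_bio(labels)
    if (nrow(sp) == 0) character(0) else paste(i, sp[, 1], sp[, 2])
  }
  g <- unlist(lapply(seq_along(gold_labels),
                     function(i) keyify(gold_labels[[i]], i)))
  p <- unlist(lapply(seq_along(pred_labels),
                     function(i) keyify(pred_labels[[i]], i)))
  inter <- length(intersect(g, p))
  if (inter == 0) return(0)
  prec <- inter / length(p)
  rec <- inter / length(g)
  2 * prec * rec / (prec + rec)
}

random_bio <- function(n) {
  labs <- character(n)
  prev_entity <- FALSE
  for (i in seq_len(n)) {
    labs[i] <- if (prev_entity) {
      sample(c("B", "I", "O"), 1, prob = c(0.15, 0.35, 0.5))
    } else {
      sample(c("B", "O"), 1, prob = c(0.25, 0.75))
    }
    prev_entity <- labs[i] != "O"
  }
  labs
}
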