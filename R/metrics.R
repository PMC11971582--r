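# SemEval-2013 Task 9 "Type" matching: a predicted span matches a gold
# span iff the entity types are equal and the character intervals
# overlap by at least one character; the assignment is one-to-one.
# Matching is computed as a maximum bipartite matching per type
# (augmenting paths seeded greedily left-to-right by gold start, ties
# to larger overlap), so correct/spurious/missing counts are always the
# optimum — a purely greedy pass can strand a matchable pair.

match_one_type <- function(gs, ge, ps, pe) {
  ng <- length(gs); np <- length(ps)
  match_g <- integer(ng)  # gold i -> pred index (0 = unmatched)
  match_p <- integer(np)
  overlap <- function(i, j) min(ge[i], pe[j]) - max(gs[i], ps[j])
  # greedy seed in spec order
  for (i in order(gs, ge)) {
    ovs <- vapply(seq_len(np), function(j)
      if (match_p[j] == 0L) overlap(i, j) else -Inf, 0)
    if (np > 0L && max(ovs) > 0) {
      j <- which(ovs == max(ovs))[1L]
      match_g[i] <- j; match_p[j] <- i
    }
  }
  # augmenting paths (Kuhn) for remaining gold
  try_augment <- function(i, visited) {
    for (j in seq_len(np)) {
      if (visited[j] || overlap(i, j) <= 0) next
      visited[j] <- TRUE
      if (match_p[j] == 0L) {
        match_g[i] <<- j; match_p[j] <<- i
        return(list(ok = TRUE, visited = visited))
      }
      res <- try_augment(match_p[j], visited)
      visited <- res$visited
      if (res$ok) {
        match_g[i] <<- j; match_p[j] <<- i
        return(list(ok = TRUE, visited = visited))
      }
    }
    list(ok = FALSE, visited = visited)
  }
  for (i in seq_len(ng)) {
    if (match_g[i] == 0L) try_augment(i, rep(FALSE, np))
  }
  match_g
}

#' Type-match gold and predicted spans for one note
#'
#' Implements the Type NER evaluation mode: a prediction is credited
#' when its entity type equals the gold type and the spans overlap by
#' at least one character; matched pairs are one-to-one.
#'
#' @param gold,pred Entity-span tables (see [entity_spans()]).
#' @return A list of class `cr_match` with `counts` (a `data.frame`
#'   with per-type `correct`, `spurious`, `missing`, `support`) and
#'   `pairs` (matched gold/pred row indices).
#' @export
match_type <- function(gold, pred) {
  counts <- data.frame(etype = ENTITY_TYPES, correct = 0L, spurious = 0L,
                       missing = 0L, support = 0L,
                       stringsAsFactors = FALSE)
  pairs <- list()
  for (t in seq_along(ENTITY_TYPES)) {
    ty <- ENTITY_TYPES[t]
    gi <- which(gold$etype == ty)
    pi <- which(pred$etype == ty)
    mg <- match_one_type(gold$start[gi], gold$end[gi],
                         pred$start[pi], pred$end[pi])
    n_match <- sum(mg > 0L)
    counts$correct[t] <- n_match
    counts$missing[t] <- length(gi) - n_match
    counts$spurious[t] <- length(pi) - n_match
    counts$support[t] <- length(gi)
    if (n_match > 0L) {
      hit <- which(mg > 0L)
      pairs[[ty]] <- data.frame(gold_row = gi[hit], pred_row = pi[mg[hit]])
    }
  }
  structure(list(counts = counts, pairs = pairs), class = "cr_match")
}

#' Precision/recall/F1 from Type-match results
#'
#' Aggregates per-note match counts over a corpus. Per type:
#' P = correct / (correct + spurious), R = correct / (correct +
#' missing), F1 their harmonic mean. A type with no gold and no
#' predicted spans scores P = R = F1 = 1 (vacuous truth; the `support`
#' column makes such types visible). The `micro` row pools counts over
#' all five types.
#'
#' @param results A `cr_match` or list of them.
#' @return A `data.frame` with rows per type plus `"micro"`, columns
#'   `etype`, `precision`, `recall`, `f1`, `correct`, `spurious`,
#'   `missing`, `support`.
#' @export
ner_f1 <- function(results) {
  if (inherits(results, "cr_match")) results <- list(results)
  if (length(results) == 0L) stop("no match results", call. = FALSE)
  agg <- Reduce(function(a, b) {
    a[, -1] <- a[, -1] + b[, -1]; a
  }, lapply(results, function(r) r$counts))
  total <- data.frame(etype = "micro", t(colSums(agg[, -1])),
                      stringsAsFactors = FALSE)
  agg <- rbind(agg, total)
  for (cl in c("correct", "spurious", "missing", "support"))
    agg[[cl]] <- as.integer(agg[[cl]])
  prf <- function(c_, s_, m_) {
    p <- if (c_ + s_ == 0L) 1 else c_ / (c_ + s_)
    r <- if (c_ + m_ == 0L) 1 else c_ / (c_ + m_)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p, r, f)
  }
  met <- t(mapply(prf, agg$correct, agg$spurious, agg$missing))
  data.frame(etype = agg$etype, precision = met[, 1], recall = met[, 2],
             f1 = met[, 3], agg[, -1], stringsAsFactors = FALSE)
}

check_binary <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels
}

#' Area under the ROC curve
#'
#' Computed by the midrank (Mann-Whitney) formula: the probability that
#' a random positive outscores a random negative, ties counted 1/2.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector; both classes required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) summation over descending score
#' thresholds, with no linear interpolation between PR points: tied
#' scores enter as a block.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- check_binary(scores, labels)
  n_pos <- sum(labels)
  if (n_pos == 0L)
    stop("AUPRC undefined: no positive labels", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp_prev <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    prec <- tp / sum(pred)
    ap <- ap + (tp - tp_prev) / n_pos * prec
    tp_prev <- tp
  }
  ap
}

#' Percentile-bootstrap confidence interval for a score-based metric
#'
#' Resamples (score, label) pairs with replacement; resamples on which
#' the metric is undefined (single-class draws) are redrawn.
#'
#' @param metric_fn Function `(scores, labels) -> number`, e.g.
#'   [auroc()].
#' @param scores,labels As for the metric.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Named vector `estimate`, `ci_low`, `ci_high`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 2000L,
                         conf = 0.95, seed = 1L) {
  set.seed(seed)
  n <- length(scores)
  est <- metric_fn(scores, labels)
  vals <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metric_fn(scores[idx], labels[idx]),
                    error = function(e) NA_real_)
      if (!is.na(v)) break
    }
    vals[b] <- v
  }
  alpha <- (1 - conf) / 2
  q <- quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(estimate = est, ci_low = q[1], ci_high = q[2])
}

#' Per-class and macro F1 for three-level D predictions
#'
#' One-vs-rest precision/recall/F1 for each D level plus their
#' unweighted (macro) mean.
#'
#' @param pred,gold Integer vectors with values in `{0, 1, 2}`.
#' @return A `data.frame` with rows `D0`, `D1`, `D2`, `macro`.
#' @export
d_class_f1 <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  rows <- lapply(0:2, function(cl) {
    tp <- sum(pred == cl & gold == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(pred != cl & gold == cl)
    p <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    r <- if (tp + fn == 0L) 1 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    data.frame(class = paste0("D", cl), precision = p, recall = r,
               f1 = f, support = sum(gold == cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(class = "macro", precision = mean(out$precision),
                        recall = mean(out$recall), f1 = mean(out$f1),
                        support = length(gold), stringsAsFactors = FALSE))
}
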