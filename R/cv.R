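#' Stratified k-fold assignment
#'
#' Partitions indices into k folds so that per-fold class counts differ
#' from perfect stratification by at most 1: within each class, items
#' are shuffled and dealt round-robin from a random starting fold.
#' Deterministic given the seed.
#'
#' @param labels Class label vector (one per item).
#' @param k Number of folds, `2 <= k <= length(labels)`.
#' @param seed Integer seed.
#' @param ids Optional item identifiers; defaults to indices.
#' @return A list of class `cr_folds` with `k`, `assignment` (named
#'   integer vector, values in `1..k`) and `seed`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L, ids = NULL) {
  n <- length(labels)
  k <- as.integer(k)
  if (k > n) stop("k must not exceed the number of items", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    start <- sample.int(k, 1L)
    fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k) + 1L
  }
  structure(list(k = k, assignment = setNames(fold, ids), seed = seed),
            class = "cr_folds")
}

#' Leakage-free k-fold cross-validation
#'
#' For each fold, the trainer sees only the notes of the other folds —
#' the test fold is withheld by construction — and the metric function
#' evaluates the fitted model on the withheld fold. Reports per-fold
#' metric values, their mean, and a 95% confidence interval across
#' folds (mean +/- t(0.975, k-1) * SE).
#'
#' @param corpus List of [annotated_note()] objects.
#' @param k Number of folds.
#' @param trainer Function `(train_corpus, seed) -> model`.
#' @param metric Function `(model, test_corpus) -> named numeric
#'   vector`.
#' @param seed Integer seed (drives fold assignment and per-fold
#'   trainer seeds).
#' @param stratify_by Note field used for stratification (default
#'   `"d_gold"`), or a function of a note returning a label.
#' @return A list of class `cr_eval` with `per_fold` (k x m matrix),
#'   `mean`, `ci_low`, `ci_high` and `folds`.
#' @export
cross_validate <- function(corpus, k, trainer, metric, seed = 1L,
                           stratify_by = "d_gold") {
  lab_fn <- if (is.function(stratify_by)) stratify_by
            else function(note) note[[stratify_by]] %||% 0L
  labels <- vapply(corpus, function(n) as.character(lab_fn(n)), "")
  ids <- vapply(corpus, `[[`, "", "note_id")
  folds <- stratified_kfold(labels, k, seed = seed, ids = ids)
  per_fold <- NULL
  for (f in seq_len(k)) {
    test_idx <- which(folds$assignment == f)
    train_corpus <- corpus[-test_idx]
    model <- trainer(train_corpus, seed + f)
    vals <- metric(model, corpus[test_idx])
    if (is.null(per_fold))
      per_fold <- matrix(NA_real_, nrow = k, ncol = length(vals),
                         dimnames = list(NULL, names(vals)))
    per_fold[f, ] <- vals
  }
  m <- colMeans(per_fold)
  se <- apply(per_fold, 2, sd) / sqrt(k)
  tq <- qt(0.975, df = k - 1)
  structure(list(per_fold = per_fold, mean = m,
                 ci_low = m - tq * se, ci_high = m + tq * se,
                 folds = folds),
            class = "cr_eval")
}

#' @export
print.cr_eval <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$folds$k))
  for (nm in names(x$mean))
    cat(sprintf("  %s: %.4f [%.4f, %.4f]\n", nm, x$mean[nm],
                x$ci_low[nm], x$ci_high[nm]))
  invisible(x)
}

#' Score a corpus with the NER + logic D pipeline
#'
#' Tags each note with the recognizer, applies the deterministic
#' entity-to-D logic, and tabulates against gold labels when present.
#'
#' @param model A `cr_recognizer`.
#' @param corpus List of notes.
#' @return A `data.frame` with `note_id`, `unique_dx_count`,
#'   `prior_count`, `d_score` and (when available) `d_gold`.
#' @export
score_corpus_d <- function(model, corpus) {
  rows <- lapply(corpus, function(note) {
    spans <- predict_entities(model, note$text)
    br <- d_score_from_entities(spans)
    data.frame(note_id = note$note_id,
               unique_dx_count = br$unique_dx_count,
               prior_count = br$prior_count, d_score = br$d_score,
               d_gold = if (is.null(note$d_gold)) NA_integer_
                        else note$d_gold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
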