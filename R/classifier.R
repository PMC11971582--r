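#' Text-augmentation parameters
#'
#' Defaults follow the training recipe the pipeline uses for
#' low-resource fine-tuning: 15 words each of synonym replacement,
#' random insertion and random swap, then random word deletion with
#' 15% per-word probability.
#'
#' @param n_synonym,n_insert,n_swap Nonnegative operation counts
#'   (capped at the number of eligible words at apply time).
#' @param p_delete Per-word deletion probability in `[0, 1]`.
#' @return A list of class `cr_augment`.
#' @export
augment_params <- function(n_synonym = 15L, n_insert = 15L, n_swap = 15L,
                           p_delete = 0.15) {
  stopifnot(n_synonym >= 0, n_insert >= 0, n_swap >= 0,
            p_delete >= 0, p_delete <= 1)
  structure(list(n_synonym = as.integer(n_synonym),
                 n_insert = as.integer(n_insert),
                 n_swap = as.integer(n_swap), p_delete = p_delete),
            class = "cr_augment")
}

#' Runtime text augmentation
#'
#' Applies, in order: synonym replacement (from the packaged synonym
#' table), random word insertion, random word swap, then per-word
#' random deletion. Operation counts are capped at the number of
#' eligible words; zero-intensity parameters return the input
#' unchanged. Uses the current RNG state — seed upstream for
#' reproducibility. Character offsets are not preserved, so
#' augmentation is only applied to classifier training text, never to
#' span-annotated text.
#'
#' @param text A single string.
#' @param params An [augment_params()].
#' @param synonyms Named character vector mapping words to replacements.
#' @return The augmented string.
#' @export
augment_text <- function(text, params = augment_params(),
                         synonyms = default_lexicons()$synonyms) {
  if (params$n_synonym == 0L && params$n_insert == 0L &&
      params$n_swap == 0L && params$p_delete == 0) {
    return(text)
  }
  words <- strsplit(trimws(text), "[ \t\r\n]+")[[1]]
  if (length(words) == 0L) return(text)
  if (params$n_synonym > 0L) {
    elig <- which(tolower(words) %in% names(synonyms))
    if (length(elig) > 0L) {
      pick <- sample_indices(elig, min(params$n_synonym, length(elig)))
      words[pick] <- unname(synonyms[tolower(words[pick])])
    }
  }
  if (params$n_insert > 0L) {
    n_ins <- min(params$n_insert, length(words))
    pool <- unname(synonyms)
    for (w in sample(pool, n_ins, replace = TRUE)) {
      pos <- sample.int(length(words) + 1L, 1L)
      words <- append(words, w, after = pos - 1L)
    }
  }
  if (params$n_swap > 0L && length(words) >= 2L) {
    for (s in seq_len(min(params$n_swap, length(words)))) {
      ij <- sample.int(length(words), 2L)
      words[ij] <- words[rev(ij)]
    }
  }
  if (params$p_delete > 0) {
    words <- words[runif(length(words)) >= params$p_delete]
  }
  paste(words, collapse = " ")
}

# sample() with the length-1 gotcha avoided
sample_indices <- function(x, n) {
  if (length(x) == 1L) return(rep_len(x, min(n, 1L)))
  sample(x, n)
}

#' Inverse-class-frequency oversampling
#'
#' Draws example indices with replacement, each example weighted by the
#' inverse frequency of its class, so expected per-class totals are
#' equal (random minority oversampling).
#'
#' @param labels Class label vector (any atomic type).
#' @param n_draws Number of draws.
#' @param seed Integer seed; the same seed reproduces the multiset.
#' @return Integer vector of indices into `labels`, length `n_draws`.
#' @export
oversample_indices <- function(labels, n_draws, seed = 1L) {
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  counts <- table(labels)
  w <- 1 / as.numeric(counts[as.character(labels)])
  set.seed(seed)
  sample.int(length(labels), n_draws, replace = TRUE, prob = w)
}

#' Select an operating threshold
#'
#' Exhaustive search over candidate thresholds (the unique observed
#' scores) for the one maximizing the criterion; ties break toward the
#' higher threshold. The default criterion is F1 of the positive class
#' (labels are predicted positive when `score >= threshold`);
#' `"youden"` maximizes sensitivity + specificity - 1.
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param labels Logical (or 0/1) vector; both classes must be present.
#' @param criterion `"f1"` (default) or `"youden"`.
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels, criterion = c("f1", "youden")) {
  criterion <- match.arg(criterion)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to select a threshold",
         call. = FALSE)
  cand <- sort(unique(scores))
  vals <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    if (criterion == "f1") {
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    } else {
      tp / (tp + fn) + tn / (tn + fp) - 1
    }
  }, 0)
  best <- max(vals)
  max(cand[vals >= best - 1e-12])
}

ovr_label <- function(note, target) {
  switch(target,
         D0 = note$d_gold == 0L,
         D2 = note$d_gold == 2L,
         EA2 = note$ea_gold == 2L,
         stop("unknown target: ", target, call. = FALSE))
}

bow_matrix <- function(texts, vocab = NULL, gazetteer = NULL) {
  raw <- lapply(texts, function(t) {
    w <- tolower(strsplit(trimws(t), "[^A-Za-z0-9]+")[[1]])
    w[nzchar(w)]
  })
  # unigrams plus token bigrams: multiword phrases then carry their own
  # features, so a linear model can count distinct phrases
  tok <- lapply(raw, function(w) {
    if (length(w) < 2L) w
    else c(w, paste0(w[-length(w)], "_", w[-1]))
  })
  all_tok <- unlist(tok, use.names = FALSE)
  if (is.null(vocab)) vocab <- sort(unique(all_tok))
  row_idx <- rep(seq_along(tok), lengths(tok))
  col_idx <- match(all_tok, vocab)
  keep <- !is.na(col_idx)
  counts <- Matrix::sparseMatrix(i = row_idx[keep], j = col_idx[keep],
                                 x = 1, dims = c(length(tok), length(vocab)))
  # token counts plus binary presence block: a linear model over both
  # can represent "number of distinct phrases present" as well as
  # mention counts
  X <- cbind(counts, 1 * (counts > 0))
  if (!is.null(gazetteer)) {
    # pooled gazetteer features per entity class: total, distinct and
    # repeated token counts. Individual domain words are too rare at
    # desk-scale corpus sizes for per-word weights; pooling makes
    # "how many distinct diagnosis words" a single dense feature.
    pool <- matrix(0, nrow = length(raw), ncol = 3L * length(ENTITY_TYPES))
    colnames(pool) <- paste0(rep(ENTITY_TYPES, each = 3L), "_",
                             c("total", "distinct", "repeat"))
    for (i in seq_along(raw)) {
      g <- gazetteer[raw[[i]]]
      g <- g[!is.na(g)]
      if (length(g) == 0L) next
      for (t in seq_along(ENTITY_TYPES)) {
        ty <- ENTITY_TYPES[t]
        n_tot <- sum(g == ty)
        n_dis <- length(unique(names(g)[g == ty]))
        pool[i, 3L * t - 2L] <- n_tot
        pool[i, 3L * t - 1L] <- n_dis
        pool[i, 3L * t] <- n_tot - n_dis
      }
    }
    X <- cbind(X, pool)
  }
  list(X = X, vocab = vocab)
}

#' Train a one-vs-rest note classifier
#'
#' Fits the reference backend — regularized logistic regression over
#' bag-of-words features (unigram and bigram counts, binary presence
#' indicators, and per-entity-class pooled gazetteer counts) — for one
#' binary target: `D0` (D = 0 vs
#' rest), `D2` (D = 2 vs rest) or `EA2` (EA = 2 vs EA0/EA1, the binary
#' EA model). Optional runtime augmentation perturbs each training
#' example per [augment_text()]; optional oversampling draws training
#' examples with inverse-class-frequency weights. The stored operating
#' threshold is selected on the training scores with
#' [select_threshold()] (refit it on held-out data via
#' [set_threshold()] for honest operating points). Backends are
#' registered by name so heavier models can implement the same
#' contract.
#'
#' @param corpus List of [annotated_note()] objects with the gold label
#'   the target needs (`d_gold` or `ea_gold`).
#' @param target `"D0"`, `"D2"` or `"EA2"`.
#' @param hyper Named list; recognized: `lambda` (default 0.01),
#'   `alpha` (elastic-net mixing, default 0.5), `lexicons` (gazetteer
#'   source, default [default_lexicons()]), `gazetteer = FALSE` to
#'   disable pooled gazetteer features, `backend` (default
#'   `"bow_glmnet"`).
#' @param augment An [augment_params()] or `NULL` (off).
#' @param oversample Logical; inverse-class-frequency oversampling.
#' @param seed Integer seed; training is deterministic given it.
#' @return An object of class `cr_ovr`.
#' @export
train_ovr <- function(corpus, target = c("D0", "D2", "EA2"),
                      hyper = list(), augment = NULL, oversample = FALSE,
                      seed = 1L) {
  target <- match.arg(target)
  backend <- hyper$backend %||% "bow_glmnet"
  trainer <- get_backend(backend)
  y <- vapply(corpus, ovr_label, NA, target = target)
  if (anyNA(y)) stop("missing gold labels for target ", target, call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training corpus contains a single class for target ", target,
         call. = FALSE)
  set.seed(seed)
  texts <- vapply(corpus, `[[`, "", "text")
  idx <- if (oversample) {
    oversample_indices(y, n_draws = 2L * length(y),
                       seed = sample.int(.Machine$integer.max, 1L))
  } else {
    seq_along(y)
  }
  train_texts <- texts[idx]
  if (!is.null(augment))
    train_texts <- vapply(train_texts, augment_text, "", params = augment)
  fitted <- trainer(train_texts, y[idx], hyper)
  model <- structure(list(target = target, backend = backend,
                          fitted = fitted, threshold = 0.5,
                          training_meta = list(
                            seed = seed, hyper = hyper,
                            augment = augment, oversample = oversample,
                            n_train = length(idx))),
                     class = "cr_ovr")
  scores <- backend_score(model, texts)
  model$threshold <- select_threshold(scores, y)
  model
}

# --- backend registry -------------------------------------------------

backend_registry <- new.env(parent = emptyenv())

#' Register a classifier backend
#'
#' A backend is a function `(texts, labels, hyper) -> fitted` paired
#' with a scorer `(fitted, texts) -> scores in [0, 1]`. The reference
#' backend `"bow_glmnet"` is registered at load time; heavier backends
#' (e.g. transformer fine-tunes) can be slotted in under a new name
#' without changing the training surface.
#'
#' @param name Backend identifier.
#' @param train,score Backend functions.
#' @export
register_backend <- function(name, train, score) {
  assign(name, list(train = train, score = score), envir = backend_registry)
  invisible(name)
}

get_backend <- function(name) {
  if (!exists(name, envir = backend_registry, inherits = FALSE))
    stop("unknown classifier backend: ", name, call. = FALSE)
  get(name, envir = backend_registry, inherits = FALSE)$train
}

backend_score <- function(model, texts) {
  sc <- get(model$backend, envir = backend_registry,
            inherits = FALSE)$score
  sc(model$fitted, texts)
}

bow_glmnet_train <- function(texts, labels, hyper) {
  lambda <- hyper$lambda %||% 0.01
  alpha <- hyper$alpha %||% 0.5
  gaz <- if (isFALSE(hyper$gazetteer)) NULL
         else gazetteer_words(hyper$lexicons %||% default_lexicons())
  bm <- bow_matrix(texts, gazetteer = gaz)
  fit <- glmnet::glmnet(bm$X, factor(labels, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = alpha,
                        lambda = c(1, 0.1, lambda), standardize = FALSE)
  list(fit = fit, vocab = bm$vocab, gazetteer = gaz, lambda = lambda)
}

bow_glmnet_score <- function(fitted, texts) {
  X <- bow_matrix(texts, vocab = fitted$vocab,
                  gazetteer = fitted$gazetteer)$X
  as.numeric(predict(fitted$fit, X, s = fitted$lambda, type = "response"))
}

register_backend("bow_glmnet", bow_glmnet_train, bow_glmnet_score)

#' @export
print.cr_ovr <- function(x, ...) {
  cat(sprintf("One-vs-rest %s classifier (backend %s), threshold %.3f\n",
              x$target, x$backend, x$threshold))
  invisible(x)
}

#' Score notes with a one-vs-rest classifier
#'
#' @param object A `cr_ovr` model.
#' @param newdata List of notes (or character vector of texts).
#' @param ... Unused.
#' @return A `data.frame` with columns `note_id`, `score` in `[0, 1]`
#'   and `label` (`score >= threshold`).
#' @export
predict.cr_ovr <- function(object, newdata, ...) {
  if (length(newdata) == 0L)
    return(data.frame(note_id = character(), score = numeric(),
                      label = logical(), stringsAsFactors = FALSE))
  if (is.character(newdata)) {
    ids <- as.character(seq_along(newdata))
    texts <- newdata
  } else {
    ids <- vapply(newdata, `[[`, "", "note_id")
    texts <- vapply(newdata, `[[`, "", "text")
  }
  scores <- backend_score(object, texts)
  data.frame(note_id = ids, score = scores,
             label = scores >= object$threshold, stringsAsFactors = FALSE)
}

#' Refit the stored operating threshold
#'
#' Scores a validation corpus and stores the threshold maximizing the
#' criterion there.
#'
#' @param model A `cr_ovr` model.
#' @param validation List of labelled notes.
#' @inheritParams select_threshold
#' @return The model with an updated threshold.
#' @export
set_threshold <- function(model, validation, criterion = "f1") {
  y <- vapply(validation, ovr_label, NA, target = model$target)
  scores <- predict(model, validation)$score
  model$threshold <- select_threshold(scores, y, criterion)
  model
}

#' Full stepwise D pipeline from two one-vs-rest models
#'
#' Applies the thresholded D0 and D2 classifiers and composes their
#' decisions with [stepwise_d()].
#'
#' @param model_d0,model_d2 `cr_ovr` models for targets D0 and D2.
#' @param notes List of notes.
#' @return A `data.frame` with `note_id`, `d0_score`, `d2_score`,
#'   `d_pred` in `{0, 1, 2}`.
#' @export
predict_stepwise_d <- function(model_d0, model_d2, notes) {
  p0 <- predict(model_d0, notes)
  p2 <- predict(model_d2, notes)
  data.frame(note_id = p0$note_id, d0_score = p0$score,
             d2_score = p2$score,
             d_pred = stepwise_d(p0$label, p2$label),
             stringsAsFactors = FALSE)
}

#' Save / load a classifier
#'
#' @param model A `cr_ovr` model.
#' @param dir Model directory.
#' @return `dir` / the model.
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(target = model$target, backend = model$backend,
               threshold = model$threshold)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  saveRDS(model, file.path(dir, "parameters.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  readRDS(file.path(dir, "parameters.rds"))
}
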