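test_that("zero-intensity augmentation is the identity", {
  zero <- augment_params(0, 0, 0, 0)
  set.seed(3)
  for (r in 1:50) {
    n_words <- sample(1:40, 1)
    text <- paste(sample(letters, n_words, replace = TRUE), collapse = " ")
    expect_identical(augment_text(text, zero), text)
  }
  expect_identical(augment_text("", zero), "")
})

test_that("word deletion matches binomial moments", {
  params <- augment_params(0, 0, 0, 0.15)
  text <- paste(rep("word", 1000), collapse = " ")
  set.seed(7)
  retained <- vapply(1:50, function(i) {
    out <- augment_text(text, params)
    if (!nzchar(out)) 0L else length(strsplit(out, " ")[[1]])
  }, 0L)
  expect_lt(abs(mean(retained) - 850), 3 * sqrt(1000 * 0.15 * 0.85) / sqrt(50))
  # boundary: delete everything
  expect_identical(augment_text("a b c", augment_params(0, 0, 0, 1)), "")
})

test_that("augmentation operations respect caps and synonym table", {
  syn <- c(fever = "pyrexia")
  set.seed(5)
  out <- augment_text("fever fever", augment_params(10, 0, 0, 0),
                      synonyms = syn)
  expect_identical(out, "pyrexia pyrexia")
  # swap preserves the multiset of words
  set.seed(6)
  out2 <- augment_text("a b c d e", augment_params(0, 0, 3, 0))
  expect_setequal(strsplit(out2, " ")[[1]], c("a", "b", "c", "d", "e"))
  # insertion adds exactly min(n_insert, n_words) words
  set.seed(7)
  out3 <- augment_text("a b c", augment_params(0, 10, 0, 0), synonyms = syn)
  expect_identical(length(strsplit(out3, " ")[[1]]), 6L)
})

test_that("inverse-frequency oversampling balances expected class mass", {
  labels <- rep(c("A", "B"), c(90, 10))
  idx <- oversample_indices(labels, 10000, seed = 11)
  expect_identical(oversample_indices(labels, 10000, seed = 11), idx)
  frac_b <- mean(labels[idx] == "B")
  expect_lt(abs(frac_b - 0.5), 3 * sqrt(0.25 / 10000))
  # balanced labels reduce to uniform weights
  bal <- rep(c("A", "B"), each = 50)
  w <- table(bal[oversample_indices(bal, 20000, seed = 2)])
  expect_lt(abs(w[["A"]] - 10000), 3 * sqrt(20000 * 0.25))
  expect_error(oversample_indices(character(), 10), "empty")
})

test_that("threshold selection maximizes F1 with ties to the higher cut", {
  expect_identical(select_threshold(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1)),
                   0.35)
  # perfectly separated: candidate rule returns the lowest positive score
  expect_identical(select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)),
                   0.8)
  expect_error(select_threshold(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("threshold selection agrees with brute-force search", {
  brute <- function(scores, labels, crit) {
    cand <- sort(unique(scores))
    f <- vapply(cand, function(t) {
      pred <- scores >= t
      tp <- sum(pred & labels); fp <- sum(pred & !labels)
      fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
      if (crit == "f1") {
        p <- if (tp + fp == 0) 0 else tp / (tp + fp)
        r <- if (tp + fn == 0) 0 else tp / (tp + fn)
        if (p + r == 0) 0 else 2 * p * r / (p + r)
      } else {
        tp / (tp + fn) + tn / (tn + fp) - 1
      }
    }, 0)
    max(cand[f >= max(f) - 1e-12])
  }
  set.seed(13)
  for (r in 1:40) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 3)
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    for (crit in c("f1", "youden"))
      expect_identical(select_threshold(scores, labels, crit),
                       brute(scores, labels, crit))
  }
})

test_that("one-vs-rest training is deterministic and rejects one-class data", {
  corpus <- generate_corpus(generator_config(120, seed = 47))
  m1 <- train_ovr(corpus[1:90], "D2", seed = 8)
  m2 <- train_ovr(corpus[1:90], "D2", seed = 8)
  p1 <- predict(m1, corpus[91:120])
  expect_identical(p1, predict(m2, corpus[91:120]))
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_identical(p1$label, p1$score >= m1$threshold)
  only_pos <- Filter(function(n) n$d_gold == 2L, corpus)
  expect_error(train_ovr(only_pos, "D2"), "single class")
  expect_identical(nrow(predict(m1, list())), 0L)
})

test_that("augmentation and oversampling compose with training", {
  corpus <- generate_corpus(generator_config(150, seed = 53))
  m <- train_ovr(corpus[1:110], "EA2", augment = augment_params(),
                 oversample = TRUE, seed = 9)
  p <- predict(m, corpus[111:150])
  y <- vapply(corpus[111:150], function(n) n$ea_gold == 2L, NA)
  expect_gte(auroc(p$score, y), 0.8)
  expect_identical(m$training_meta$oversample, TRUE)
})

test_that("threshold refit on validation data updates the stored cut", {
  corpus <- generate_corpus(generator_config(140, seed = 59))
  m <- train_ovr(corpus[1:100], "D0", seed = 10)
  m2 <- set_threshold(m, corpus[101:140])
  expect_true(m2$threshold >= 0 && m2$threshold <= 1)
  p <- predict(m2, corpus[101:140])
  expect_identical(p$label, p$score >= m2$threshold)
})

test_that("stepwise pipeline emits labels in {0,1,2}", {
  corpus <- generate_corpus(generator_config(160, seed = 61))
  m0 <- train_ovr(corpus[1:120], "D0", seed = 1)
  m2 <- train_ovr(corpus[1:120], "D2", seed = 1)
  out <- predict_stepwise_d(m0, m2, corpus[121:160])
  expect_true(all(out$d_pred %in% 0:2))
  acc <- mean(out$d_pred == vapply(corpus[121:160], `[[`, 0L, "d_gold"))
  expect_gt(acc, 0.6)
})

test_that("classifier serialization round-trips scores and threshold", {
  corpus <- generate_corpus(generator_config(80, seed = 67))
  m <- train_ovr(corpus[1:60], "D2", seed = 2)
  dir <- withr::local_tempdir()
  save_classifier(m, dir)
  back <- load_classifier(dir)
  expect_identical(predict(back, corpus[61:80]), predict(m, corpus[61:80]))
  expect_identical(back$threshold, m$threshold)
})

test_that("unknown backends are rejected and new ones can be registered", {
  corpus <- generate_corpus(generator_config(40, seed = 71))
  expect_error(train_ovr(corpus, "D0", hyper = list(backend = "llm")),
               "unknown classifier backend")
  register_backend("constant",
                   train = function(texts, labels, hyper) mean(labels),
                   score = function(fitted, texts)
                     rep(fitted, length(texts)))
  m <- train_ovr(corpus, "D0", hyper = list(backend = "constant"))
  expect_true(all(predict(m, corpus[1:3])$score == m$fitted))
})
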