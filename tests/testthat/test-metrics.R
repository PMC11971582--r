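test_that("type matching demands type equality and character overlap", {
  txt <- paste(rep("x", 40), collapse = "")
  gold <- entity_spans(c(15), c(30), "Dx", span_surface(txt, 15, 30))
  pred <- entity_spans(c(10), c(20), "Dx", span_surface(txt, 10, 20))
  m <- match_type(gold, pred)
  expect_identical(m$counts$correct[m$counts$etype == "Dx"], 1L)

  pred_dc <- entity_spans(c(10), c(20), "DC", span_surface(txt, 10, 20))
  gold_dx <- entity_spans(c(10), c(20), "Dx", span_surface(txt, 10, 20))
  m2 <- match_type(gold_dx, pred_dc)
  expect_identical(m2$counts$missing[m2$counts$etype == "Dx"], 1L)
  expect_identical(m2$counts$spurious[m2$counts$etype == "DC"], 1L)
  expect_identical(sum(m2$counts$correct), 0L)

  # adjacent but non-overlapping intervals never match
  pred_adj <- entity_spans(c(30), c(35), "Dx", span_surface(txt, 30, 35))
  m3 <- match_type(gold, pred_adj)
  expect_identical(sum(m3$counts$correct), 0L)

  # identity yields all-correct
  m4 <- match_type(gold, gold)
  f <- ner_f1(m4)
  expect_identical(f$f1[f$etype == "micro"], 1)
})

test_that("matching is one-to-one", {
  txt <- paste(rep("x", 50), collapse = "")
  gold <- entity_spans(c(0, 10), c(8, 20), c("Dx", "Dx"),
                       span_surface(txt, c(0, 10), c(8, 20)))
  pred <- entity_spans(5, 15, "Dx", span_surface(txt, 5, 15))
  m <- match_type(gold, pred)
  expect_identical(m$counts$correct[1], 1L)
  expect_identical(m$counts$missing[1], 1L)
  expect_identical(m$counts$spurious[1], 0L)
})

test_that("match counts agree with the exhaustive matching oracle", {
  set.seed(73)
  for (r in 1:80) {
    gold <- random_spans(40L, sample(0:6, 1))
    pred <- random_spans(40L, sample(0:6, 1))
    m <- match_type(gold, pred)
    oracle <- oracle_match_counts(gold, pred)
    expect_identical(m$counts$correct, oracle$correct)
    expect_identical(m$counts$support, oracle$support)
    expect_identical(m$counts$correct + m$counts$missing,
                     oracle$support)
    pred_per_type <- vapply(ENTITY_TYPES, function(ty)
      sum(pred$etype == ty), 0L)
    expect_identical(m$counts$correct + m$counts$spurious,
                     unname(pred_per_type))
  }
})

test_that("precision/recall/F1 follow the count formulas and conventions", {
  txt <- paste(rep("x", 60), collapse = "")
  gold <- entity_spans(c(0, 20), c(10, 30), c("Dx", "Dx"),
                       span_surface(txt, c(0, 20), c(10, 30)))
  pred <- entity_spans(c(0, 20, 40), c(10, 30, 50), c("Dx", "Dx", "Dx"),
                       span_surface(txt, c(0, 20, 40), c(10, 30, 50)))
  f <- ner_f1(match_type(gold, pred))
  dx <- f[f$etype == "Dx", ]
  expect_equal(dx$precision, 2 / 3)
  expect_equal(dx$recall, 1)
  expect_equal(dx$f1, 0.8)
  # vacuous types score 1 with zero support
  dc <- f[f$etype == "DC", ]
  expect_identical(dc$f1, 1)
  expect_identical(dc$support, 0L)
  # no predictions, some gold: recall and F1 are 0
  f2 <- ner_f1(match_type(gold, entity_spans()))
  expect_identical(f2$recall[f2$etype == "Dx"], 0)
  expect_identical(f2$f1[f2$etype == "Dx"], 0)
  expect_true(all(f$f1 <= pmax(f$precision, f$recall) + 1e-12))
})

test_that("AUROC equals the all-pairs probability and resists monotone maps", {
  expect_identical(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  pair_oracle <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b)
      ifelse(a > b, 1, ifelse(a == b, 0.5, 0)))
    mean(cmp)
  }
  set.seed(79)
  for (r in 1:60) {
    n <- sample(4:50, 1)
    scores <- round(runif(n), 2)  # rounded to force ties
    labels <- as.integer(runif(n) < 0.5)
    if (length(unique(labels)) < 2) next
    a <- auroc(scores, labels)
    expect_equal(a, pair_oracle(scores, labels), tolerance = 1e-9)
    expect_equal(auroc(qlogis((scores + 1) / 3), labels), a,
                 tolerance = 1e-9)
    expect_equal(auroc(scores * 100 + 7, labels), a, tolerance = 1e-9)
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  scores <- runif(200)
  labels <- as.integer(runif(200) < 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-9)
})

test_that("AUPRC uses step-wise average precision", {
  expect_identical(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # single positive ranked first
  expect_identical(auprc(c(0.99, 0.5, 0.4), c(1, 0, 0)), 1)
  # hand-computed: positives at ranks 1 and 3
  # AP = (1/2) * (1/1) + (1/2) * (2/3)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 0.5 + 1 / 3)
  # random scores converge to the positive rate
  set.seed(89)
  n <- 10000
  labels <- as.integer(runif(n) < 0.3)
  scores <- runif(n)
  expect_lt(abs(auprc(scores, labels) - 0.3), 0.03)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "no positive")
})

test_that("bootstrap CI brackets the point estimate deterministically", {
  set.seed(97)
  scores <- c(runif(60, 0.4, 1), runif(60, 0, 0.6))
  labels <- rep(c(1, 0), each = 60)
  ci <- bootstrap_ci(auroc, scores, labels, n_boot = 300, seed = 7)
  expect_lte(ci[["ci_low"]], ci[["estimate"]])
  expect_gte(ci[["ci_high"]], ci[["estimate"]])
  expect_identical(ci, bootstrap_ci(auroc, scores, labels,
                                    n_boot = 300, seed = 7))
})

test_that("per-class D F1 matches hand-computed confusion counts", {
  gold <- c(0, 0, 1, 1, 2, 2)
  pred <- c(0, 1, 1, 1, 2, 0)
  f <- d_class_f1(pred, gold)
  # D0: tp=1 fp=1 fn=1 -> P=R=F1=0.5
  expect_equal(f$f1[f$class == "D0"], 0.5)
  # D1: tp=2 fp=1 fn=0 -> P=2/3, R=1, F1=0.8
  expect_equal(f$f1[f$class == "D1"], 0.8)
  # D2: tp=1 fp=0 fn=1 -> P=1, R=0.5, F1=2/3
  expect_equal(f$f1[f$class == "D2"], 2 / 3)
  expect_equal(f$f1[f$class == "macro"], mean(c(0.5, 0.8, 2 / 3)))
})
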