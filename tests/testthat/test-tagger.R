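test_that("tokenizer records exact character offsets", {
  toks <- tokenize_offsets("Likely CHF, vs pneumonia.")
  expect_identical(toks$token, c("Likely", "CHF", ",", "vs", "pneumonia", "."))
  expect_identical(substring("Likely CHF, vs pneumonia.",
                             toks$start + 1L, toks$end), toks$token)
  expect_identical(nrow(tokenize_offsets("")), 0L)
  expect_identical(nrow(tokenize_offsets("   ")), 0L)
})

test_that("dictionary tagger finds lexicon phrases at their offsets", {
  dict <- dictionary_recognizer()
  text <- "patient with suspected pneumonia today"
  s <- predict_entities(dict, text)
  expect_identical(nrow(s), 1L)
  expect_identical(s$etype, "Dx")
  expect_identical(s$surface, "pneumonia")
  expect_identical(span_surface(text, s$start, s$end), "pneumonia")
  # word boundaries: no match inside a longer word
  expect_identical(nrow(predict_entities(dict, "pseudopneumonias")), 0L)
  expect_identical(nrow(predict_entities(dict, "")), 0L)
})

test_that("oracle recognizer replays gold spans and warns on unseen text", {
  corpus <- tiny_corpus()
  oracle <- oracle_recognizer(corpus)
  expect_identical(predict_entities(oracle, corpus[[1]]$text),
                   corpus[[1]]$spans)
  expect_warning(out <- predict_entities(oracle, "never seen"), "unseen")
  expect_identical(nrow(out), 0L)
})

test_that("oracle composed with the D logic reproduces generator labels", {
  corpus <- generate_corpus(generator_config(60, seed = 17))
  oracle <- oracle_recognizer(corpus)
  scored <- score_corpus_d(oracle, corpus)
  expect_identical(scored$d_score, scored$d_gold)
})

test_that("training is reproducible and learns the easy regime", {
  corpus <- generate_corpus(generator_config(150, seed = 19))
  train <- corpus[1:110]; test <- corpus[111:150]
  m1 <- train_tagger(train, seed = 4)
  m2 <- train_tagger(train, seed = 4)
  probe <- vapply(test[1:5], `[[`, "", "text")
  for (tx in probe)
    expect_identical(predict_entities(m1, tx), predict_entities(m2, tx))
  f1 <- ner_f1(lapply(test, function(n)
    match_type(n$spans, predict_entities(m1, n$text))))
  expect_gte(f1$f1[f1$etype == "micro"], 0.9)
  expect_identical(nrow(predict_entities(m1, "")), 0L)
})

test_that("a corpus with no spans of one type trains with a warning", {
  corpus <- generate_corpus(generator_config(25, seed = 23))
  stripped <- lapply(corpus, function(n) {
    n$spans <- n$spans[n$spans$etype != "Link", , drop = FALSE]
    rownames(n$spans) <- NULL
    n$ea_gold <- ea_score_from_entities(n$text, n$spans)
    n
  })
  ws <- capture_warnings(m <- train_tagger(stripped, seed = 1))
  expect_match(ws, "Link", all = FALSE)
  expect_s3_class(m, "cr_tagger")
})

test_that("predicted spans always satisfy the span invariants", {
  corpus <- generate_corpus(generator_config(120, seed = 29))
  m <- train_tagger(corpus[1:90], seed = 1)
  dict <- dictionary_recognizer()
  set.seed(31)
  texts <- c(vapply(corpus[91:120], `[[`, "", "text"),
             "random words entirely outside any lexicon",
             "pneumonia pneumonia pneumonia",
             "most likely gout, most likely asthma")
  for (model in list(m, dict)) {
    for (tx in texts) {
      s <- predict_entities(model, tx)
      if (nrow(s) == 0L) next
      expect_true(all(s$start >= 0L & s$start < s$end &
                        s$end <= nchar(tx)))
      expect_identical(s$surface, span_surface(tx, s$start, s$end))
      expect_false(is.unsorted(s$start))
      if (nrow(s) > 1L)
        expect_true(all(s$start[-1] >= head(s$end, -1)))
      expect_true(all(s$etype %in% ENTITY_TYPES))
    }
  }
})

test_that("recognizer serialization round-trips to an identical predictor", {
  corpus <- generate_corpus(generator_config(60, seed = 37))
  m <- train_tagger(corpus[1:45], seed = 2)
  dir <- withr::local_tempdir()
  save_recognizer(m, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  back <- load_recognizer(dir)
  for (n in corpus[46:60])
    expect_identical(predict_entities(back, n$text),
                     predict_entities(m, n$text))
  expect_error(save_recognizer(oracle_recognizer(corpus), dir),
               "not serializable")
})

test_that("reference tagger beats the dictionary baseline under span noise", {
  cfg <- generator_config(260, noise = 0.12, noise_in_spans = TRUE,
                          seed = 43)
  corpus <- generate_corpus(cfg)
  train <- corpus[1:200]; test <- corpus[201:260]
  m <- train_tagger(train, seed = 5)
  dict <- dictionary_recognizer()
  f_tag <- ner_f1(lapply(test, function(n)
    match_type(n$spans, predict_entities(m, n$text))))
  f_dic <- ner_f1(lapply(test, function(n)
    match_type(n$spans, predict_entities(dict, n$text))))
  expect_gt(f_tag$f1[f_tag$etype == "micro"],
            f_dic$f1[f_dic$etype == "micro"])
})
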