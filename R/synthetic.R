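# Synthetic assessment-section notes with gold spans and gold labels.
# The generator and the rubric logic share one implementation
# (d_score_from_entities / ea_score_from_entities), so gold labels are
# consistent with the scorer by construction, and that consistency is
# still checked exhaustively in the tests.

#' Configuration for the synthetic-note generator
#'
#' Class proportions default to the retrospective development note set
#' the generator emulates: D score 15.6% / 22% / 62.4% and EA score
#' 10.4% / 36.4% / 53.1% for levels 0/1/2.
#'
#' @param n_notes Number of notes to generate.
#' @param d_proportions,ea_proportions Nonnegative 3-vectors summing to
#'   1: target class proportions for levels 0, 1, 2.
#' @param lexicons Named list of phrase lists as produced by
#'   [default_lexicons()].
#' @param noise Character-level misspelling/casing rate in `[0, 1]`,
#'   applied outside gold spans (default 0: the "easy" regime).
#' @param noise_in_spans If `TRUE`, noise is also applied inside gold
#'   spans (the "hard" regime); span surfaces are updated to match.
#' @param seed Integer seed; the same config generates a byte-identical
#'   corpus.
#' @return A list of class `cr_genconfig`.
#' @export
generator_config <- function(n_notes,
                             d_proportions = c(109, 154, 437) / 700,
                             ea_proportions = c(73, 255, 372) / 700,
                             lexicons = default_lexicons(),
                             noise = 0, noise_in_spans = FALSE,
                             seed = 1L) {
  cfg <- structure(list(n_notes = as.integer(n_notes),
                        d_proportions = d_proportions,
                        ea_proportions = ea_proportions,
                        lexicons = lexicons, noise = noise,
                        noise_in_spans = isTRUE(noise_in_spans),
                        seed = as.integer(seed)),
                   class = "cr_genconfig")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  for (p in list(cfg$d_proportions, cfg$ea_proportions)) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("proportions must be a nonnegative 3-vector summing to 1",
           call. = FALSE)
  }
  lex <- cfg$lexicons
  for (ty in ENTITY_TYPES)
    if (length(lex[[ty]]) == 0L)
      stop("empty lexicon for entity type ", ty, call. = FALSE)
  pairs <- utils::combn(ENTITY_TYPES, 2)
  for (j in seq_len(ncol(pairs))) {
    ov <- intersect(lex[[pairs[1, j]]], lex[[pairs[2, j]]])
    if (length(ov) > 0L)
      stop(sprintf("lexicons %s and %s overlap: %s", pairs[1, j],
                   pairs[2, j], ov[1]), call. = FALSE)
  }
  if (cfg$n_notes < 1L) stop("n_notes must be positive", call. = FALSE)
  if (cfg$noise < 0 || cfg$noise > 1)
    stop("noise must be in [0, 1]", call. = FALSE)
  if (sum(cfg$d_proportions[2:3]) > 0 && length(lex$Dx) < 2L)
    stop("D1/D2 notes require at least 2 Dx lexicon entries", call. = FALSE)
  if (cfg$d_proportions[3] > 0 && length(lex$Prior) < 1L)
    stop("D2 notes require a non-empty Prior lexicon", call. = FALSE)
  invisible(cfg)
}

# Mutable sentence builder: accumulates text and 0-based span offsets.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- character()
  env$len <- 0L
  env$spans <- list()
  env
}

emit <- function(b, text) {
  b$pieces[[length(b$pieces) + 1L]] <- text
  b$len <- b$len + nchar(text)
  invisible(b)
}

emit_span <- function(b, phrase, etype) {
  b$spans[[length(b$spans) + 1L]] <-
    list(start = b$len, end = b$len + nchar(phrase), etype = etype)
  emit(b, phrase)
}

builder_spans <- function(b, text) {
  if (length(b$spans) == 0L) return(entity_spans())
  st <- vapply(b$spans, `[[`, 0L, "start")
  en <- vapply(b$spans, `[[`, 0L, "end")
  ty <- vapply(b$spans, `[[`, "", "etype")
  entity_spans(st, en, ty, span_surface(text, st, en))
}

#' Sample one synthetic annotated note
#'
#' Constructs assessment-section prose whose gold spans realize the
#' requested D and EA scores. D2 notes contain at least 2 distinct
#' diagnosis phrases plus prioritization language; D0 notes contain at
#' most 1 unique diagnosis (possibly alongside diagnostic-category
#' words, which never count toward D). EA targets are realized by
#' placing Data and Link phrases in the sentences of the required
#' number of diagnosis mentions; when EA > 0 is requested together with
#' D0, the single unique diagnosis is mentioned in several sentences.
#'
#' Uses the current RNG state; seed upstream (as [generate_corpus()]
#' does) for reproducibility.
#'
#' @param d_target,ea_target Requested scores in `{0, 1, 2}`.
#' @param config A [generator_config()].
#' @param note_id Identifier for the generated note.
#' @return An [annotated_note()] with gold spans, `d_gold` and
#'   `ea_gold` computed from the spans by the shared rubric logic.
#' @export
sample_note <- function(d_target, ea_target, config,
                        note_id = "synthetic_note") {
  stopifnot(d_target %in% 0:2, ea_target %in% 0:2)
  lex <- config$lexicons
  n_unique <- if (d_target == 0L) {
    if (ea_target > 0L) 1L else sample(0:1, 1L, prob = c(0.3, 0.7))
  } else {
    sample(2:min(3L, length(lex$Dx)), 1L)
  }
  dx_forms <- if (n_unique > 0L) sample(lex$Dx, n_unique) else character()
  # One sentence per mention; extra mentions of the first diagnosis are
  # added when more evidence sentences are needed than unique diagnoses.
  n_evid <- ea_target
  mention_dx <- dx_forms
  while (length(mention_dx) < n_evid)
    mention_dx <- c(mention_dx, dx_forms[1L])
  evid <- rep(FALSE, length(mention_dx))
  if (n_evid > 0L) evid[sample.int(length(mention_dx), n_evid)] <- TRUE
  n_prior <- if (d_target == 2L) sample(1:2, 1L, prob = c(0.7, 0.3))
             else if (d_target == 0L && runif(1) < 0.3) 1L else 0L
  with_dc <- runif(1) < if (d_target == 0L) 0.6 else 0.35

  b <- new_builder()
  if (runif(1) < 0.6) {
    emit(b, sample(lex$distractor, 1L)); emit(b, ". ")
  }
  if (with_dc) {
    emit(b, "this presentation appears ")
    emit_span(b, sample(lex$DC, 1L), "DC")
    emit(b, " in origin. ")
  }
  for (i in seq_along(mention_dx)) {
    if (evid[i]) {
      emit(b, "exam and labs show ")
      emit_span(b, sample(lex$Data, 1L), "Data")
      emit(b, ", ")
      emit_span(b, sample(lex$Link, 1L), "Link")
      emit(b, " ")
      emit_span(b, mention_dx[i], "Dx")
      emit(b, ". ")
    } else {
      emit(b, "we also consider ")
      emit_span(b, mention_dx[i], "Dx")
      emit(b, " here. ")
    }
  }
  if (n_prior > 0L) {
    prior_phrases <- sample(lex$Prior, n_prior)
    for (p in prior_phrases) {
      emit(b, "the ")
      emit_span(b, p, "Prior")
      if (n_unique > 0L) {
        emit(b, " remains ")
        emit_span(b, dx_forms[1L], "Dx")
      } else {
        emit(b, " remains undetermined")
      }
      emit(b, ". ")
    }
  }
  if (runif(1) < 0.3) {
    emit(b, "she reports ")
    emit_span(b, sample(lex$Data, 1L), "Data")
    emit(b, " today. ")
  }
  if (runif(1) < 0.4 || b$len == 0L) {
    emit(b, sample(lex$distractor, 1L)); emit(b, ".")
  }
  text <- trimws(paste(b$pieces, collapse = ""), which = "right")
  spans <- builder_spans(b, text)
  if (config$noise > 0)
    return(apply_noise(text, spans, config, note_id))
  finish_note(text, spans, note_id)
}

finish_note <- function(text, spans, note_id) {
  annotated_note(note_id = note_id, text = text, spans = spans,
                 site = "synthetic",
                 d_gold = d_score_from_entities(spans)$d_score,
                 ea_gold = ea_score_from_entities(text, spans))
}

# Character-level substitution/casing noise. Only letters are eligible
# (periods and spaces are structural); offsets never shift.
apply_noise <- function(text, spans, config, note_id) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  in_span <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(spans)))
    in_span[(spans$start[i] + 1L):spans$end[i]] <- TRUE
  eligible <- grepl("[a-zA-Z]", chars) &
    (config$noise_in_spans | !in_span)
  hit <- eligible & runif(length(chars)) < config$noise
  for (j in which(hit)) {
    chars[j] <- if (runif(1) < 0.5) toupper(chars[j])
                else sample(letters, 1L)
  }
  text <- paste(chars, collapse = "")
  spans$surface <- span_surface(text, spans$start, spans$end)
  finish_note(text, spans, note_id)
}

#' Generate a synthetic annotated corpus
#'
#' Draws per-note D and EA targets from the configured class
#' proportions and builds each note with [sample_note()]. Gold labels
#' equal the rubric logic applied to the gold spans; the same
#' configuration and seed always produce a byte-identical corpus.
#'
#' @param config A [generator_config()].
#' @return A list of [annotated_note()] objects of length
#'   `config$n_notes`.
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_notes
  d_targets <- sample(0:2, n, replace = TRUE, prob = config$d_proportions)
  ea_targets <- sample(0:2, n, replace = TRUE, prob = config$ea_proportions)
  corpus <- vector("list", n)
  for (i in seq_len(n)) {
    corpus[[i]] <- sample_note(d_targets[i], ea_targets[i], config,
                               note_id = sprintf("note_%05d", i))
  }
  validate_corpus(corpus)
  corpus
}
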