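# Small in-code fixtures shared across test files.

# Build an entity-span table from triplets; surfaces are sliced from
# the text so invariants hold by construction.
sp <- function(text, ...) {
  trips <- list(...)
  st <- vapply(trips, `[[`, 0, 1)
  en <- vapply(trips, `[[`, 0, 2)
  ty <- vapply(trips, `[[`, "", 3)
  entity_spans(st, en, ty, span_surface(text, st, en))
}

# A tiny two-note annotated corpus with known labels.
tiny_corpus <- function() {
  t1 <- "exam and labs show fever, consistent with pneumonia. most likely pneumonia."
  t2 <- "we also consider gout here. we also consider asthma here."
  list(
    annotated_note("n1", t1,
                   spans = sp(t1, list(19, 24, "Data"),
                              list(26, 41, "Link"), list(42, 51, "Dx"),
                              list(53, 64, "Prior"), list(65, 74, "Dx")),
                   d_gold = 0L, ea_gold = 1L),
    annotated_note("n2", t2,
                   spans = sp(t2, list(17, 21, "Dx"), list(45, 51, "Dx")),
                   d_gold = 1L, ea_gold = 0L))
}

# Random span set over a text of given length: n spans, possibly
# overlapping, random types. Used for matcher property tests.
random_spans <- function(text_len, n) {
  if (n == 0L) return(entity_spans())
  st <- sample.int(text_len - 1L, n, replace = TRUE) - 1L
  len <- sample.int(8L, n, replace = TRUE)
  en <- pmin(st + len, text_len)
  txt <- paste(rep("x", text_len), collapse = "")
  entity_spans(st, en, sample(ENTITY_TYPES, n, replace = TRUE),
               span_surface(txt, st, en))
}

# Exhaustive maximum one-to-one Type matching over all assignments:
# the independent oracle for the greedy+augmenting matcher.
oracle_match_counts <- function(gold, pred) {
  per_type <- lapply(ENTITY_TYPES, function(ty) {
    gi <- which(gold$etype == ty)
    pi <- which(pred$etype == ty)
    ng <- length(gi); np <- length(pi)
    if (ng == 0L || np == 0L) return(0L)
    edge <- outer(seq_len(ng), seq_len(np), Vectorize(function(i, j) {
      min(gold$end[gi[i]], pred$end[pi[j]]) -
        max(gold$start[gi[i]], pred$start[pi[j]]) > 0
    }))
    best <- 0L
    # enumerate injections gold -> pred
    rec <- function(i, used, matched) {
      if (matched + (ng - i + 1L) <= best) return()
      if (i > ng) { best <<- max(best, matched); return() }
      rec(i + 1L, used, matched)
      for (j in seq_len(np)) {
        if (!used[j] && edge[i, j]) {
          used[j] <- TRUE
          rec(i + 1L, used, matched + 1L)
          used[j] <- FALSE
        }
      }
    }
    rec(1L, rep(FALSE, np), 0L)
    best
  })
  data.frame(etype = ENTITY_TYPES,
             correct = vapply(per_type, identity, 0L),
             support = vapply(ENTITY_TYPES,
                              function(ty) sum(gold$etype == ty), 0L))
}
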