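#' Normalize a diagnosis surface form
#'
#' Uniqueness of diagnoses is defined on normalized surface forms:
#' Unicode case-folding, stripping of leading/trailing punctuation, and
#' collapsing of internal whitespace. No synonym or ontology merging is
#' applied by default ("CHF" and "congestive heart failure" count as
#' two diagnoses); pass a `synonym_map` to merge forms explicitly.
#'
#' @param x Character vector of surface forms.
#' @param synonym_map Optional named character vector mapping normalized
#'   forms to canonical forms.
#' @return Character vector of normalized forms.
#' @export
normalize_dx_form <- function(x, synonym_map = NULL) {
  out <- tolower(x)
  out <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", out)
  out <- gsub("[[:space:]]+", " ", out)
  if (!is.null(synonym_map)) {
    hit <- out %in% names(synonym_map)
    out[hit] <- unname(synonym_map[out[hit]])
  }
  out
}

#' Count unique diagnoses among entity spans
#'
#' Counts distinct normalized `Dx` surface forms. Spans of the other
#' four types (`DC`, `Prior`, `Data`, `Link`) never contribute: a
#' diagnostic category such as "cardiac" is not a diagnosis.
#'
#' @param spans An entity-span table (see [entity_spans()]).
#' @param synonym_map Passed to [normalize_dx_form()].
#' @return A list with `count` (integer) and `forms` (character vector
#'   of distinct normalized forms, in order of first appearance).
#' @export
count_unique_dx <- function(spans, synonym_map = NULL) {
  dx <- spans$surface[spans$etype == "Dx"]
  forms <- unique(normalize_dx_form(dx, synonym_map))
  list(count = length(forms), forms = forms)
}

#' Differential-diagnosis (D) score from entity spans
#'
#' Deterministic logic mapping entities to the Revised-IDEA D score:
#' D0 when the note has fewer than 2 unique diagnoses; D2 when it has
#' at least 2 unique diagnoses and explicit prioritization language
#' (at least one `Prior` span); D1 everything else.
#'
#' @inheritParams count_unique_dx
#' @return A list of class `cr_dscore` with fields `d_score` (0, 1 or
#'   2), `unique_dx_count`, `prior_count`, `dc_count` and
#'   `normalized_dx_forms`.
#' @export
d_score_from_entities <- function(spans, synonym_map = NULL) {
  dx <- count_unique_dx(spans, synonym_map)
  prior_count <- sum(spans$etype == "Prior")
  dc_count <- sum(spans$etype == "DC")
  d <- if (dx$count < 2L) 0L else if (prior_count >= 1L) 2L else 1L
  structure(list(d_score = d, unique_dx_count = dx$count,
                 prior_count = prior_count, dc_count = dc_count,
                 normalized_dx_forms = dx$forms),
            class = "cr_dscore")
}

#' @export
print.cr_dscore <- function(x, ...) {
  cat(sprintf("D%d (%d unique dx, %d prior, %d category)\n",
              x$d_score, x$unique_dx_count, x$prior_count, x$dc_count))
  invisible(x)
}

#' Stepwise composition of one-vs-rest D decisions
#'
#' Composes thresholded D0 and D2 one-vs-rest decisions into a single D
#' score by the ordered rule: (1) if the D0 model predicts D = 0, then
#' D = 0; (2) else if the D2 model predicts D = 2, then D = 2;
#' (3) else D = 1.
#'
#' @param d0_positive,d2_positive Logical vectors of thresholded
#'   one-vs-rest decisions (recycled to a common length).
#' @return Integer vector of D scores in `{0, 1, 2}`.
#' @export
stepwise_d <- function(d0_positive, d2_positive) {
  n <- max(length(d0_positive), length(d2_positive))
  d0 <- rep_len(as.logical(d0_positive), n)
  d2 <- rep_len(as.logical(d2_positive), n)
  ifelse(d0, 0L, ifelse(d2, 2L, 1L))
}

#' Binarize the EA score
#'
#' Collapses the three-level explanation-of-reasoning score into the
#' binary target actually modelled: `EA2` (full explanation) versus
#' `not_EA2` (EA0 or EA1).
#'
#' @param ea_score Integer vector with values in `{0, 1, 2}`.
#' @return Factor with levels `not_EA2`, `EA2`.
#' @export
ea2_binarize <- function(ea_score) {
  if (!all(ea_score %in% 0:2))
    stop("ea_score values must be in {0,1,2}", call. = FALSE)
  factor(ifelse(ea_score == 2L, "EA2", "not_EA2"),
         levels = c("not_EA2", "EA2"))
}

# Sentence index (0-based) of each character offset: sentences are
# delimited by '.', '!' or '?'.
sentence_index <- function(text, offsets) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bounds <- cumsum(chars %in% c(".", "!", "?"))
  idx <- ifelse(offsets == 0L, 0L, bounds[offsets])
  as.integer(idx)
}

#' Explanation-of-reasoning (EA) score from entity spans
#'
#' Generator convention for gold EA labels (the rubric's EA semantics —
#' explanation of lead and alternative diagnoses — operationalized on
#' entities): a `Dx` mention counts as *explained* when its sentence
#' also contains at least one `Data` span and at least one `Link` span.
#' EA = 0 with no explained mention, 1 with exactly one, 2 with two or
#' more.
#'
#' @param text Note text (sentences delimited by `.`, `!` or `?`).
#' @param spans An entity-span table.
#' @return Integer EA score in `{0, 1, 2}`.
#' @export
ea_score_from_entities <- function(text, spans) {
  if (nrow(spans) == 0L) return(0L)
  sent <- sentence_index(text, spans$start)
  dx_sent <- sent[spans$etype == "Dx"]
  data_sent <- unique(sent[spans$etype == "Data"])
  link_sent <- unique(sent[spans$etype == "Link"])
  explained <- sum(dx_sent %in% data_sent & dx_sent %in% link_sent)
  min(explained, 2L)
}
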