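# Assessment-section truncation. Institutions template admission notes
# differently, so the header/plan-marker vocabulary is a per-site
# "dialect" table rather than a single hard-coded rule.

#' Truncation dialects
#'
#' Header and plan-marker vocabularies for assessment-section
#' truncation. Each dialect lists assessment-section headers (matched
#' case-insensitively at line start) and plan markers that terminate the
#' differential-diagnosis discussion. The `nyu` and `uc` entries are
#' editable site profiles seeded with common templates.
#'
#' @return Named list of dialects, each with `headers` and
#'   `plan_markers` character vectors.
#' @export
truncation_dialects <- function() {
  list(
    default = list(
      headers = c("assessment and plan", "assessment & plan", "assessment",
                  "a/p", "impression"),
      plan_markers = c("plan[ \\t]*:", "[0-9]+[.)]")),
    nyu = list(
      headers = c("assessment and plan", "assessment", "impression and plan",
                  "impression", "hospital course"),
      plan_markers = c("plan[ \\t]*:", "[0-9]+[.)]", "disposition[ \\t]*:")),
    uc = list(
      headers = c("a&p", "a/p", "assessment and plan", "assessment",
                  "impression"),
      plan_markers = c("plan[ \\t]*:", "[0-9]+[.)]", "#"))
  )
}

#' Truncate a note to its assessment section
#'
#' Extracts the span from the first assessment-section header to the
#' first plan-enumeration marker, the part of an admission note that
#' concentrates on the differential diagnosis for the presenting
#' problem. When no header matches, the whole text is returned with
#' `matched_rule = "fallback_whole_note"` and a warning. The output is
#' always a contiguous substring of the input.
#'
#' @param text A single non-empty string (the full note).
#' @param dialect Name of a dialect in [truncation_dialects()], or a
#'   list with `headers` and `plan_markers`.
#' @return A list of class `cr_truncation` with fields `text`, `start`,
#'   `end` (0-based half-open offsets into the original) and
#'   `matched_rule`.
#' @export
truncate_assessment <- function(text, dialect = "default") {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("text must be a single non-empty string", call. = FALSE)
  if (is.character(dialect)) {
    tab <- truncation_dialects()
    if (!dialect %in% names(tab))
      stop("unknown dialect: ", dialect, call. = FALSE)
    dialect <- tab[[dialect]]
  }
  hdr_pat <- paste0("(?im)^[ \\t]*(",
                    paste(gsub("([&/])", "\\\\\\1", dialect$headers),
                          collapse = "|"),
                    ")[ \\t]*:?[ \\t]*")
  m <- regexpr(hdr_pat, text, perl = TRUE)
  if (m[1] == -1L) {
    warning("no assessment header matched; returning whole note",
            call. = FALSE)
    return(truncation_result(text, 0L, nchar(text), "fallback_whole_note"))
  }
  body_start <- m[1] + attr(m, "match.length")  # 1-based first body char
  matched <- sub("[[:space:]]*:?[[:space:]]*$", "",
                 trimws(substr(text, m[1], body_start - 1L)))
  rest <- substr(text, body_start, nchar(text))
  plan_pat <- paste0("(?im)^[ \\t]*(",
                     paste(dialect$plan_markers, collapse = "|"), ")")
  pm <- regexpr(plan_pat, rest, perl = TRUE)
  body_end <- if (pm[1] == -1L) nchar(text) else body_start + pm[1] - 2L
  # trim surrounding whitespace by shrinking offsets (stay contiguous)
  while (body_start <= body_end &&
         grepl("[ \t\r\n]", substr(text, body_start, body_start)))
    body_start <- body_start + 1L
  while (body_end >= body_start &&
         grepl("[ \t\r\n]", substr(text, body_end, body_end)))
    body_end <- body_end - 1L
  truncation_result(substr(text, body_start, body_end),
                    body_start - 1L, body_end,
                    paste0("header:", tolower(matched)))
}

truncation_result <- function(text, start, end, rule) {
  structure(list(text = text, start = as.integer(start),
                 end = as.integer(end), matched_rule = rule),
            class = "cr_truncation")
}

#' @export
print.cr_truncation <- function(x, ...) {
  cat(sprintf("<truncation %s [%d,%d)>\n%s\n", x$matched_rule,
              x$start, x$end, x$text))
  invisible(x)
}

#' Truncate every note in a corpus
#'
#' Applies [truncate_assessment()] to each note's text; gold spans (if
#' any) are dropped because offsets change.
#'
#' @param corpus List of [annotated_note()] objects.
#' @inheritParams truncate_assessment
#' @return Corpus of truncated notes.
#' @export
truncate_corpus <- function(corpus, dialect = "default") {
  lapply(corpus, function(note) {
    tr <- truncate_assessment(note$text, dialect)
    out <- note
    out$text <- tr$text
    out$spans <- entity_spans()
    out
  })
}
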