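#' @importFrom stats coef predict quantile rbinom rnorm runif sd qt qf pf setNames
#' @importFrom utils head modifyList write.csv
#' @importFrom glmnet glmnet
#' @importFrom Matrix sparseMatrix
#' @importFrom jsonlite fromJSON toJSON write_json
NULL

#' The five rubric entity types
#'
#' Entity types annotated in admission-note assessment sections: `Dx`
#' (specific diagnosis), `DC` (diagnostic category, e.g. "cardiac"),
#' `Prior` (prioritization language), `Data` (supporting clinical data)
#' and `Link` (linkage term connecting data to a diagnosis).
#'
#' @export
ENTITY_TYPES <- c("Dx", "DC", "Prior", "Data", "Link")

#' Construct an entity-span table
#'
#' Spans use 0-based, half-open character offsets (`start` inclusive,
#' `end` exclusive), the convention of common standoff-annotation
#' exports. `surface` must equal the corresponding slice of the note
#' text; see [span_surface()].
#'
#' @param start,end Integer vectors of character offsets.
#' @param etype Character vector of entity types (see [ENTITY_TYPES]).
#' @param surface Character vector of covered substrings.
#' @return A `data.frame` with columns `start`, `end`, `etype`,
#'   `surface`, sorted by `start`.
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         etype = character(), surface = character()) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   etype = as.character(etype),
                   surface = as.character(surface),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Extract the surface form of a 0-based half-open span
#'
#' @param text A single string.
#' @param start,end 0-based half-open offsets.
#' @return The substring `text[start:end)`.
#' @export
span_surface <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

#' Construct an annotated note
#'
#' A note bundles free text with optional gold labels and optional gold
#' entity spans; it is the unit of NER training and evaluation.
#'
#' @param note_id Unique identifier (string).
#' @param text Note text (assessment-section prose, or a full note
#'   before [truncate_assessment()]).
#' @param spans An entity-span table (see [entity_spans()]), or `NULL`.
#' @param site Optional site tag.
#' @param d_gold,ea_gold Optional gold scores in `{0, 1, 2}`.
#' @param meta Optional named list of string metadata.
#' @param ... Additional fields, preserved on round trip.
#' @return A list of class `cr_note`.
#' @export
annotated_note <- function(note_id, text, spans = NULL, site = NULL,
                           d_gold = NULL, ea_gold = NULL, meta = NULL, ...) {
  note <- list(note_id = as.character(note_id), text = as.character(text),
               site = site, d_gold = d_gold, ea_gold = ea_gold, meta = meta,
               spans = if (is.null(spans)) entity_spans() else spans)
  extra <- list(...)
  note[names(extra)] <- extra
  class(note) <- "cr_note"
  note
}

#' @export
print.cr_note <- function(x, ...) {
  cat(sprintf("<cr_note %s> %d chars, %d spans", x$note_id,
              nchar(x$text), nrow(x$spans)))
  if (!is.null(x$d_gold)) cat(sprintf(", D=%d", x$d_gold))
  if (!is.null(x$ea_gold)) cat(sprintf(", EA=%d", x$ea_gold))
  cat("\n")
  invisible(x)
}

validate_spans <- function(spans, text, note_id = "?") {
  if (nrow(spans) == 0L) return(invisible(TRUE))
  n <- nchar(text)
  bad <- spans$start < 0L | spans$end > n | spans$start >= spans$end
  if (any(bad))
    stop(sprintf("note '%s': span offsets out of range (text length %d)",
                 note_id, n), call. = FALSE)
  if (!all(spans$etype %in% ENTITY_TYPES))
    stop(sprintf("note '%s': unknown entity type(s): %s", note_id,
                 paste(setdiff(spans$etype, ENTITY_TYPES), collapse = ", ")),
         call. = FALSE)
  got <- span_surface(text, spans$start, spans$end)
  if (!identical(got, spans$surface))
    stop(sprintf("note '%s': span surface does not match text slice", note_id),
         call. = FALSE)
  if (is.unsorted(spans$start))
    stop(sprintf("note '%s': spans not sorted by start", note_id),
         call. = FALSE)
  invisible(TRUE)
}

validate_note <- function(note) {
  stopifnot(inherits(note, "cr_note"))
  for (fld in c("d_gold", "ea_gold")) {
    v <- note[[fld]]
    if (!is.null(v) && !(length(v) == 1L && v %in% 0:2))
      stop(sprintf("note '%s': %s must be in {0,1,2}", note$note_id, fld),
           call. = FALSE)
  }
  validate_spans(note$spans, note$text, note$note_id)
  invisible(TRUE)
}

#' Validate a corpus
#'
#' Checks every note against the type invariants (span offsets in range,
#' surfaces matching the text slice, labels in `{0,1,2}`) and that
#' `note_id`s are unique.
#'
#' @param corpus A list of [annotated_note()] objects.
#' @return The corpus, invisibly; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  ids <- vapply(corpus, `[[`, "", "note_id")
  if (anyDuplicated(ids))
    stop("duplicate note_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  for (note in corpus) validate_note(note)
  invisible(corpus)
}

spans_from_json <- function(x) {
  if (length(x) == 0L) return(entity_spans())
  entity_spans(start = vapply(x, function(s) as.integer(s$start), 0L),
               end = vapply(x, function(s) as.integer(s$end), 0L),
               etype = vapply(x, function(s) as.character(s$etype), ""),
               surface = vapply(x, function(s) as.character(s$surface), ""))
}

#' Read a JSONL note corpus
#'
#' One JSON object per line with fields `note_id`, `text` and optionally
#' `site`, `d_gold`, `ea_gold`, `meta` and `spans` (a list of
#' `{start, end, etype, surface}` objects with 0-based half-open
#' offsets). Unknown extra fields are preserved. Every record is
#' validated against the type invariants and file order is kept.
#'
#' @param path Path to a JSONL file.
#' @param with_annotations If `TRUE` (default) parse the `spans` field;
#'   if `FALSE` spans are dropped.
#' @return A list of [annotated_note()] objects.
#' @export
read_corpus <- function(path, with_annotations = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  corpus <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("malformed JSON on line %d: %s",
                                   i, conditionMessage(e)), call. = FALSE))
    known <- c("note_id", "text", "site", "d_gold", "ea_gold", "meta", "spans")
    extra <- rec[setdiff(names(rec), known)]
    note <- do.call(annotated_note, c(
      list(note_id = rec$note_id, text = rec$text,
           spans = if (with_annotations) spans_from_json(rec$spans) else NULL,
           site = unlist_or_null(rec$site),
           d_gold = int_or_null(rec$d_gold),
           ea_gold = int_or_null(rec$ea_gold),
           meta = rec$meta),
      extra))
    validate_note(note)
    corpus[[i]] <- note
  }
  validate_corpus(corpus)
  corpus
}

unlist_or_null <- function(x) if (is.null(x)) NULL else as.character(x)
int_or_null <- function(x) if (is.null(x)) NULL else as.integer(x)

note_to_json <- function(note) {
  rec <- list(note_id = note$note_id, text = note$text)
  for (fld in c("site", "d_gold", "ea_gold", "meta"))
    if (!is.null(note[[fld]])) rec[[fld]] <- note[[fld]]
  sp <- note$spans
  rec$spans <- lapply(seq_len(nrow(sp)), function(i)
    list(start = sp$start[i], end = sp$end[i],
         etype = sp$etype[i], surface = sp$surface[i]))
  known <- c("note_id", "text", "site", "d_gold", "ea_gold", "meta", "spans")
  extra <- setdiff(names(note), known)
  rec[extra] <- note[extra]
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a corpus as JSONL
#'
#' Inverse of [read_corpus()]: one JSON object per note, in corpus
#' order. Output is byte-identical across repeated writes of the same
#' corpus, and `read_corpus(write_corpus(x))` reproduces `x`.
#'
#' @param corpus A list of [annotated_note()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (note in corpus)
    writeLines(note_to_json(note), con, useBytes = TRUE)
  invisible(path)
}
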