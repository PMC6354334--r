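#' Construct a clinical note
#'
#' A `clinical_note` bundles the raw text of one de-identified note with its
#' standoff annotations: section spans, medical-entity spans (optionally with a
#' gold timeline index), and temporal-expression spans with normalized calendar
#' values. All spans are 0-based, half-open character intervals into `text`.
#'
#' @param note_id Unique note identifier.
#' @param text Note text (UTF-8).
#' @param sections Tibble with columns `name`, `start`, `end` and optionally
#'   `anchor`, `anchor_relation`; the anchor columns are filled from the
#'   section/anchor table (see [section_anchor_table()]) when missing.
#' @param entities Tibble with columns `me_id`, `start`, `end` and optionally
#'   `gold_index` (non-negative integer timeline ID, `NA` when unannotated).
#' @param temporal_expressions Tibble with columns `te_id`, `start`, `end`,
#'   `value` (ISO-8601 date or datetime) and `kind`
#'   (`"admission"`, `"discharge"` or `"other"`).
#' @param admission_te,discharge_te Identifiers of the admission / discharge
#'   temporal expression, or `NULL` when the note has none.
#' @param validate Run [validate_note()] on the result (default `TRUE`).
#'
#' @return An object of class `clinical_note`.
#' @export
clinical_note <- function(note_id, text, sections, entities,
                          temporal_expressions,
                          admission_te = NULL, discharge_te = NULL,
                          validate = TRUE) {
  sections <- as_tibble(sections)
  if (!"anchor" %in% names(sections) || !"anchor_relation" %in% names(sections)) {
    at <- section_anchor_table()
    idx <- match(sections$name, at$name)
    idx[is.na(idx)] <- match("Other", at$name)
    sections$anchor <- at$anchor[idx]
    sections$anchor_relation <- at$anchor_relation[idx]
  }
  entities <- as_tibble(entities)
  if (!"gold_index" %in% names(entities)) entities$gold_index <- NA_integer_
  entities$gold_index <- as.integer(entities$gold_index)
  tes <- as_tibble(temporal_expressions)
  if (!"kind" %in% names(tes)) tes$kind <- "other"
  if (nrow(entities) && !"surface" %in% names(entities)) {
    entities$surface <- span_text(text, entities$start, entities$end)
  }
  if (nrow(tes) && !"surface" %in% names(tes)) {
    tes$surface <- span_text(text, tes$start, tes$end)
  }
  note <- structure(
    list(
      note_id = as.character(note_id),
      text = enc2utf8(text),
      sections = sections,
      entities = entities,
      temporal_expressions = tes,
      admission_te = if (is.null(admission_te) || is.na(admission_te)) NULL else as.character(admission_te),
      discharge_te = if (is.null(discharge_te) || is.na(discharge_te)) NULL else as.character(discharge_te)
    ),
    class = "clinical_note"
  )
  if (validate) validate_note(note)
  note
}

# substring of `text` covered by 0-based half-open [start, end)
span_text <- function(text, start, end) {
  if (length(start) == 0) return(character())
  vapply(seq_along(start), function(i) {
    substr(text, start[i] + 1L, end[i])
  }, character(1))
}

#' Validate a clinical note's annotation invariants
#'
#' Checks that all spans are in bounds and well ordered, that entity and
#' temporal-expression spans do not cross section boundaries, that identifiers
#' are unique, that the admission/discharge identifiers resolve to temporal
#' expressions of the note, and that gold indices (when present) are valid IDs
#' of the note's timeline. Errors name the offending `note_id` and field.
#'
#' @param note A [clinical_note()].
#' @return `note`, invisibly, if valid.
#' @export
validate_note <- function(note) {
  id <- note$note_id
  n_char <- nchar(note$text)
  bad_span <- function(tbl) {
    nrow(tbl) > 0 && any(tbl$start < 0 | tbl$end > n_char | tbl$start >= tbl$end)
  }
  fail <- function(msg) abort(sprintf("note '%s': %s", id, msg),
                              class = "medtimeline_validation_error")
  for (fld in c("sections", "entities", "temporal_expressions")) {
    if (bad_span(note[[fld]])) fail(sprintf("%s span out of bounds or empty", fld))
  }
  if (anyDuplicated(note$entities$me_id)) fail("duplicate me_id")
  if (anyDuplicated(note$temporal_expressions$te_id)) fail("duplicate te_id")
  # spans must not cross section boundaries
  sec <- note$sections
  crosses <- function(s, e) {
    inside <- which(sec$start <= s & e <= sec$end)
    length(inside) == 0 && nrow(sec) > 0 &&
      any(s < sec$end & e > sec$start)  # overlaps some section partially
  }
  for (i in seq_len(nrow(note$entities))) {
    en <- note$entities[i, ]
    if (crosses(en$start, en$end)) {
      fail(sprintf("entity '%s' crosses a section boundary", en$me_id))
    }
  }
  for (i in seq_len(nrow(note$temporal_expressions))) {
    te <- note$temporal_expressions[i, ]
    if (crosses(te$start, te$end)) {
      fail(sprintf("temporal expression '%s' crosses a section boundary", te$te_id))
    }
  }
  for (fld in c("admission_te", "discharge_te")) {
    ref <- note[[fld]]
    if (!is.null(ref) && !ref %in% note$temporal_expressions$te_id) {
      fail(sprintf("%s '%s' does not refer to a temporal expression of the note", fld, ref))
    }
  }
  gi <- note$entities$gold_index
  if (any(!is.na(gi))) {
    tl <- build_timeline(note)
    valid <- timeline_ids(tl)
    bad <- !is.na(gi) & !(gi %in% valid)
    if (any(bad)) {
      fail(sprintf("gold_index %s of entity '%s' is not a valid timeline ID",
                   gi[bad][1], note$entities$me_id[bad][1]))
    }
  }
  invisible(note)
}

#' @export
print.clinical_note <- function(x, ...) {
  cat(sprintf("<clinical_note %s> %d chars, %d sections, %d entities, %d temporal expressions\n",
              x$note_id, nchar(x$text), nrow(x$sections),
              nrow(x$entities), nrow(x$temporal_expressions)))
  invisible(x)
}

new_corpus <- function(notes) {
  structure(notes, class = "mt_corpus",
            names = vapply(notes, `[[`, character(1), "note_id"))
}

#' @export
print.mt_corpus <- function(x, ...) {
  cat(sprintf("<mt_corpus> %d notes, %d entities, %d temporal expressions\n",
              length(x),
              sum(vapply(x, function(n) nrow(n$entities), integer(1))),
              sum(vapply(x, function(n) nrow(n$temporal_expressions), integer(1)))))
  invisible(x)
}

#' @export
`[.mt_corpus` <- function(x, i) new_corpus(unclass(x)[i])

#' Flatten a corpus to an entity-level tibble
#'
#' @param x An `mt_corpus`.
#' @param ... Unused.
#' @return A tibble with one row per medical entity.
#' @export
as_tibble.mt_corpus <- function(x, ...) {
  purrr::map_dfr(x, function(note) {
    if (nrow(note$entities) == 0) return(NULL)
    dplyr::mutate(note$entities, note_id = note$note_id, .before = 1)
  })
}

#' Read a JSON-lines corpus of clinical notes
#'
#' One JSON document per line, UTF-8, with fields `note_id`, `text`,
#' `sections` (name/start/end), `entities` (id/start/end and optional
#' `gold_index`), `temporal_expressions` (id/start/end/value/kind),
#' `admission_te` and `discharge_te`. Every note is validated on read;
#' a malformed line or a violated span invariant raises an error naming the
#' line or the offending note.
#'
#' @param path Path to a `.jsonl` corpus file.
#' @return An `mt_corpus` (list of [clinical_note()] objects).
#' @seealso [write_notes()] for the inverse; the two round-trip exactly.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  notes <- lapply(seq_along(lines), function(i) {
    doc <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) abort(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)),
                                class = "medtimeline_parse_error")
    )
    for (fld in c("note_id", "text", "sections", "entities", "temporal_expressions")) {
      if (is.null(doc[[fld]])) {
        abort(sprintf("line %d: missing field '%s'", i, fld),
              class = "medtimeline_parse_error")
      }
    }
    pick_chr <- function(lst, field, default = NA_character_) {
      vapply(lst, function(el) {
        v <- el[[field]]
        if (is.null(v)) default else as.character(v)
      }, character(1))
    }
    pick_int <- function(lst, field) {
      vapply(lst, function(el) {
        v <- el[[field]]
        if (is.null(v)) NA_integer_ else as.integer(v)
      }, integer(1))
    }
    secs <- tibble(
      name  = pick_chr(doc$sections, "name"),
      start = pick_int(doc$sections, "start"),
      end   = pick_int(doc$sections, "end")
    )
    ents <- tibble(
      me_id = pick_chr(doc$entities, "id"),
      start = pick_int(doc$entities, "start"),
      end   = pick_int(doc$entities, "end"),
      gold_index = pick_int(doc$entities, "gold_index")
    )
    tes <- tibble(
      te_id = pick_chr(doc$temporal_expressions, "id"),
      start = pick_int(doc$temporal_expressions, "start"),
      end   = pick_int(doc$temporal_expressions, "end"),
      value = pick_chr(doc$temporal_expressions, "value"),
      kind  = pick_chr(doc$temporal_expressions, "kind", "other")
    )
    clinical_note(doc$note_id, doc$text, secs, ents, tes,
                  admission_te = doc$admission_te,
                  discharge_te = doc$discharge_te)
  })
  new_corpus(notes)
}

#' Write a corpus as JSON lines
#'
#' Emits keys in a fixed order so that unchanged input writes bit-identical
#' output; `write_notes()` and [read_notes()] are mutually inverse on valid
#' corpora.
#'
#' @param corpus An `mt_corpus` or list of [clinical_note()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(corpus, path) {
  lines <- vapply(corpus, note_to_json, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

note_to_json <- function(note) {
  sec <- lapply(seq_len(nrow(note$sections)), function(i) {
    s <- note$sections[i, ]
    list(name = s$name, start = s$start, end = s$end)
  })
  ents <- lapply(seq_len(nrow(note$entities)), function(i) {
    e <- note$entities[i, ]
    out <- list(id = e$me_id, start = e$start, end = e$end)
    if (!is.na(e$gold_index)) out$gold_index <- e$gold_index
    out
  })
  tes <- lapply(seq_len(nrow(note$temporal_expressions)), function(i) {
    te <- note$temporal_expressions[i, ]
    list(id = te$te_id, start = te$start, end = te$end,
         value = te$value, kind = te$kind)
  })
  doc <- list(
    note_id = note$note_id,
    text = note$text,
    sections = sec,
    entities = ents,
    temporal_expressions = tes,
    admission_te = note$admission_te,
    discharge_te = note$discharge_te
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA))
}
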