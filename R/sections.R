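#' Section names and their anchor times
#'
#' Chinese clinical notes follow a fixed sectional skeleton, and each section
#' carries a characteristic "occurred time": its contents happened before, at,
#' or after either the admission or the discharge time. This table drives both
#' candidate-time selection (the section anchor is always a candidate) and the
#' rule-based baseline.
#'
#' `Diagnosis and treatment` is mapped to anchor `admission`, relation `After`
#' (the in-stay course follows admission); `Other` — any text outside a known
#' section — defaults to `admission` / `Simultaneous`.
#'
#' @return Tibble with columns `name`, `anchor` (`admission`/`discharge`) and
#'   `anchor_relation` (`Before`/`Simultaneous`/`After`).
#' @export
section_anchor_table <- function() {
  tibble(
    name = c(
      "Chief complaint", "History of present illness", "Past medical history",
      "Personal history", "Conditions in admission",
      "Physical examination", "Assistant examination", "Preliminary diagnosis",
      "Diagnosis on admission",
      "Diagnosis and treatment",
      "Conditions in discharge", "Diagnosis on discharge",
      "Discharge orders",
      "Other"
    ),
    anchor = c(rep("admission", 10), "discharge", "discharge", "discharge",
               "admission"),
    anchor_relation = c(rep("Before", 5), rep("Simultaneous", 4), "After",
                        "Simultaneous", "Simultaneous", "After", "Simultaneous")
  )
}

#' Default header lexicon
#'
#' Maps header surface strings, both the Chinese forms found in notes and
#' the English section names, to canonical section names. Users can extend it
#' via a YAML mapping file ([read_header_lexicon()]).
#'
#' @return Named character vector: header string -> section name.
#' @export
default_header_lexicon <- function() {
  zh <- c(
    "主诉" = "Chief complaint",
    "现病史" = "History of present illness",
    "既往史" = "Past medical history",
    "个人史" = "Personal history",
    "入院情况" = "Conditions in admission",
    "体格检查" = "Physical examination",
    "辅助检查" = "Assistant examination",
    "初步诊断" = "Preliminary diagnosis",
    "入院诊断" = "Diagnosis on admission",
    "诊疗经过" = "Diagnosis and treatment",
    "出院情况" = "Conditions in discharge",
    "出院诊断" = "Diagnosis on discharge",
    "出院医嘱" = "Discharge orders"
  )
  en <- section_anchor_table()$name
  en <- en[en != "Other"]
  c(zh, stats::setNames(en, en))
}

#' Read a header lexicon from a YAML mapping
#'
#' @param path YAML file mapping header strings to canonical section names.
#' @return Named character vector usable with [match_sections()].
#' @export
read_header_lexicon <- function(path) {
  m <- yaml::read_yaml(path)
  out <- vapply(m, as.character, character(1))
  stats::setNames(out, names(m))
}

#' Locate sections by matching headers at line starts
#'
#' Fallback used when the input carries no explicit section annotations.
#' Headers are matched at the start of a line (optionally followed by a colon);
#' each section runs from its header to the next matched header or the end of
#' text. Text before the first header becomes an `"Other"` section. Anchor and
#' anchor relation are filled from [section_anchor_table()].
#'
#' @param note_text Note text.
#' @param header_lexicon Named character vector mapping header surface strings
#'   to canonical section names; defaults to [default_header_lexicon()].
#' @return Tibble of sections (`name`, `start`, `end`, `anchor`,
#'   `anchor_relation`), ordered by position.
#' @export
match_sections <- function(note_text, header_lexicon = default_header_lexicon()) {
  stopifnot(length(header_lexicon) > 0)
  hits <- purrr::map_dfr(seq_along(header_lexicon), function(i) {
    hdr <- names(header_lexicon)[i]
    loc <- stringr::str_locate_all(note_text, stringr::regex(paste0("(?m)^\\Q", hdr, "\\E")))[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble(start = loc[, 1] - 1L, header = hdr, name = header_lexicon[[i]])
  })
  n_char <- nchar(note_text)
  if (nrow(hits) == 0) {
    secs <- tibble(name = "Other", start = 0L, end = n_char)
  } else {
    # a longer header wins over a shorter one matching at the same offset
    hits <- dplyr::arrange(hits, .data$start, dplyr::desc(nchar(.data$header)))
    hits <- dplyr::distinct(hits, .data$start, .keep_all = TRUE)
    starts <- hits$start
    secs <- tibble(
      name = hits$name,
      start = as.integer(starts),
      end = as.integer(c(starts[-1], n_char))
    )
    if (starts[1] > 0) {
      secs <- dplyr::bind_rows(
        tibble(name = "Other", start = 0L, end = as.integer(starts[1])), secs)
    }
  }
  at <- section_anchor_table()
  idx <- match(secs$name, at$name)
  secs$anchor <- at$anchor[idx]
  secs$anchor_relation <- at$anchor_relation[idx]
  secs
}

#' Anchor temporal expression of a section
#'
#' Returns the identifier of the admission or discharge temporal expression
#' the section's contents are timed against.
#'
#' @param section One-row tibble (or list) with an `anchor` field.
#' @param note The [clinical_note()] owning the section.
#' @return A `te_id`.
#' @export
section_anchor_te <- function(section, note) {
  anchor <- section$anchor
  te <- if (identical(anchor, "discharge")) note$discharge_te else note$admission_te
  if (is.null(te)) {
    abort(sprintf("note '%s': section '%s' requires the %s temporal expression, which is absent",
                  note$note_id, section$name, anchor),
          class = "medtimeline_anchor_error")
  }
  te
}

# section index (row number in note$sections) containing a span; NA if none
section_of_span <- function(note, start, end) {
  sec <- note$sections
  hit <- which(sec$start <= start & end <= sec$end)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
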