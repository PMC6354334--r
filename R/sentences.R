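#' Segment a note into sentences
#'
#' Splits each section on the terminators `。！？；?!;` and newline, with the
#' terminator attached to the preceding sentence. A split point falling inside
#' an annotated entity or temporal-expression span is suppressed, so
#' annotations are never cut (dates such as `2011-9-13` stay whole even when
#' punctuation-like characters occur inside them). Fragments containing only
#' whitespace or terminators are merged into the preceding sentence, so the
#' sentence spans of a section tile it exactly.
#'
#' @param note A [clinical_note()] with populated sections.
#' @return Tibble with columns `sentence_index` (0-based, note-wide), `start`,
#'   `end` (0-based half-open), and `section` (row index into
#'   `note$sections`).
#' @export
segment_sentences <- function(note) {
  terminators <- c("。", "！", "？", "；", "?", "!", ";", "\n")
  protected <- rbind(
    as.matrix(note$entities[, c("start", "end"), drop = FALSE]),
    as.matrix(note$temporal_expressions[, c("start", "end"), drop = FALSE])
  )
  chars <- strsplit(note$text, "", fixed = FALSE)[[1]]
  out <- list()
  sent_i <- 0L
  for (si in seq_len(nrow(note$sections))) {
    sec <- note$sections[si, ]
    if (sec$end <= sec$start) next
    idx <- seq.int(sec$start + 1L, sec$end)   # 1-based char positions
    is_term <- chars[idx] %in% terminators
    # candidate break after position p (0-based end offset p)
    breaks <- sec$start + which(is_term)      # 0-based half-open ends
    if (nrow(protected) > 0 && length(breaks) > 0) {
      inside <- vapply(breaks, function(b) {
        any(protected[, 1] < b & b < protected[, 2])
      }, logical(1))
      breaks <- breaks[!inside]
    }
    bounds <- unique(c(sec$start, breaks, sec$end))
    bounds <- bounds[bounds >= sec$start & bounds <= sec$end]
    bounds <- sort(bounds)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    keep_start <- NULL
    for (k in seq_along(starts)) {
      frag <- substr(note$text, starts[k] + 1L, ends[k])
      content <- gsub(paste0("[", paste(terminators, collapse = ""), "[:space:]]"),
                      "", frag)
      if (nzchar(content)) {
        if (!is.null(keep_start)) {
          out[[length(out) + 1L]] <- c(keep_start, starts[k])  # flush previous
        }
        keep_start <- starts[k]
      }
      # fragments without content extend the previous sentence (or the next
      # one when the section begins with them)
    }
    if (!is.null(keep_start)) {
      out[[length(out) + 1L]] <- c(keep_start, sec$end)
    } else if (length(starts) > 0) {
      out[[length(out) + 1L]] <- c(sec$start, sec$end)  # all-whitespace section
    }
    # re-attach leading empty fragments and record section/tiling
    n_new <- length(out) - sent_i
    if (n_new > 0) out[[sent_i + 1L]][1] <- sec$start
    for (k in seq_len(n_new)) {
      s <- out[[sent_i + k]]
      out[[sent_i + k]] <- list(start = s[1], end = s[2], section = si)
    }
    sent_i <- length(out)
  }
  if (length(out) == 0) {
    return(tibble(sentence_index = integer(), start = integer(),
                  end = integer(), section = integer()))
  }
  tibble(
    sentence_index = seq_along(out) - 1L,
    start = as.integer(vapply(out, `[[`, numeric(1), "start")),
    end = as.integer(vapply(out, `[[`, numeric(1), "end")),
    section = as.integer(vapply(out, `[[`, numeric(1), "section"))
  )
}

# sentence row (1-based into the segment_sentences tibble) containing a span
sentence_of_span <- function(sentences, start, end) {
  hit <- which(sentences$start <= start & end <= sentences$end)
  if (length(hit) == 0) NA_integer_ else hit[1]
}
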