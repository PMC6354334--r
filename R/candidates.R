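#' Candidate times for one medical entity
#'
#' The candidate set of an entity is its section's anchor time (admission or
#' discharge, per [section_anchor_table()]) plus every temporal expression
#' whose span lies inside the entity's section — anchor first, then section
#' expressions in text order, deduplicated.
#'
#' @param me_id Entity identifier.
#' @param note A [clinical_note()].
#' @param timeline Optional pre-built [build_timeline()] result (rebuilt when
#'   `NULL`); used to compute `covered` when the entity has a gold index.
#' @return A list of class `mt_candidate_set`: `me_id`, `candidates`
#'   (character vector of `te_id`s), `covered` (logical, `NA` without a gold
#'   index).
#' @export
candidates_for_entity <- function(me_id, note, timeline = NULL) {
  me <- note$entities[note$entities$me_id == me_id, ]
  if (nrow(me) == 0) {
    abort(sprintf("note '%s' has no entity '%s'", note$note_id, me_id))
  }
  sec_i <- section_of_span(note, me$start, me$end)
  if (is.na(sec_i)) {
    abort(sprintf("note '%s': entity '%s' lies outside every section",
                  note$note_id, me_id),
          class = "medtimeline_candidate_error")
  }
  sec <- note$sections[sec_i, ]
  anchor <- section_anchor_te(sec, note)
  tes <- note$temporal_expressions
  in_sec <- tes$te_id[tes$start >= sec$start & tes$end <= sec$end]
  in_sec <- in_sec[order(tes$start[match(in_sec, tes$te_id)])]
  cands <- unique(c(anchor, in_sec))
  covered <- NA
  if (!is.na(me$gold_index)) {
    if (is.null(timeline)) timeline <- build_timeline(note)
    nodes <- vapply(cands, te_node_id, integer(1), timeline = timeline)
    covered <- any(abs(me$gold_index - nodes) <= 1L)
  }
  structure(list(me_id = me_id, candidates = cands, covered = covered),
            class = "mt_candidate_set")
}

#' All candidate (entity, time) pairs of a corpus
#'
#' Expands every entity's candidate set into one row per (entity, temporal
#' expression) pair — the instance universe that relation classifiers are
#' trained and evaluated on. When gold indices are present, the gold relation
#' label of each pair is derived with [gold_relation_for_pair()].
#'
#' @param corpus An `mt_corpus`.
#' @return Tibble with columns `note_id`, `me_id`, `te_id`, `cand_rank`
#'   (1 = section anchor), and `gold_relation` (`NA` when the entity has no
#'   gold index).
#' @export
candidate_pairs <- function(corpus) {
  purrr::map_dfr(corpus, function(note) {
    if (nrow(note$entities) == 0) return(NULL)
    tl <- build_timeline(note)
    purrr::map_dfr(note$entities$me_id, function(me_id) {
      cs <- candidates_for_entity(me_id, note, tl)
      gi <- note$entities$gold_index[note$entities$me_id == me_id]
      tibble(
        note_id = note$note_id,
        me_id = me_id,
        te_id = cs$candidates,
        cand_rank = seq_along(cs$candidates),
        gold_relation = if (is.na(gi)) NA_character_ else
          vapply(cs$candidates, gold_relation_for_pair, character(1),
                 gold_index = gi, timeline = tl)
      )
    })
  })
}

#' Coverage of the candidate-selection method
#'
#' An entity is *covered* when its gold index is reachable from at least one
#' of its candidate times via SIMULTANEOUS, BEFORE or AFTER. On noise-free
#' synthetic corpora coverage is exactly 1.
#'
#' @param corpus An `mt_corpus` whose entities carry gold indices.
#' @return A list of class `mt_coverage_report`: `coverage` (fraction),
#'   `n_entities`, `n_covered`, `total_pairs`, `mean_candidates`.
#' @export
coverage_report <- function(corpus) {
  if (length(corpus) == 0) {
    abort("empty corpus", class = "medtimeline_candidate_error")
  }
  covered <- integer(0)
  sizes <- integer(0)
  for (note in corpus) {
    tl <- build_timeline(note)
    for (me_id in note$entities$me_id) {
      cs <- candidates_for_entity(me_id, note, tl)
      covered <- c(covered, as.integer(cs$covered))
      sizes <- c(sizes, length(cs$candidates))
    }
  }
  if (length(covered) == 0 || all(is.na(covered))) {
    abort("corpus has no entities with gold indices",
          class = "medtimeline_candidate_error")
  }
  structure(list(
    coverage = mean(covered, na.rm = TRUE),
    n_entities = length(covered),
    n_covered = sum(covered, na.rm = TRUE),
    total_pairs = sum(sizes),
    mean_candidates = mean(sizes)
  ), class = "mt_coverage_report")
}

#' @export
print.mt_coverage_report <- function(x, ...) {
  cat("Candidate selection coverage\n")
  cat(sprintf("  %-18s %d\n", "entities", x$n_entities))
  cat(sprintf("  %-18s %d\n", "covered", x$n_covered))
  cat(sprintf("  %-18s %.4f\n", "coverage", x$coverage))
  cat(sprintf("  %-18s %d\n", "selected pairs", x$total_pairs))
  cat(sprintf("  %-18s %.2f\n", "mean candidates", x$mean_candidates))
  invisible(x)
}

#' @export
tidy.mt_coverage_report <- function(x, ...) {
  tibble(coverage = x$coverage, n_entities = x$n_entities,
         n_covered = x$n_covered, total_pairs = x$total_pairs,
         mean_candidates = x$mean_candidates)
}
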