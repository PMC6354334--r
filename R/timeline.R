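#' Build the per-note timeline
#'
#' All temporal expressions of a note are sorted by normalized value; mentions
#' sharing one value collapse into a single *time node*. Nodes receive the odd
#' IDs 1, 3, ..., 2n-1 in ascending time order, and the n+1 *time intervals*
#' around them receive the even IDs 0, 2, ..., 2n — ID 0 is the interval before
#' the first node, ID 2n the interval after the last. A note with no temporal
#' expression has the single interval ID 0.
#'
#' @param note A [clinical_note()]; every temporal expression must carry a
#'   normalized `value`.
#' @return An `mt_timeline`: list with `nodes` (tibble `node_id`, `value`,
#'   `te_ids` list-column) and `n_nodes`.
#' @export
build_timeline <- function(note) {
  tes <- note$temporal_expressions
  missing_val <- is.na(tes$value) | !nzchar(tes$value)
  if (any(missing_val)) {
    abort(sprintf("note '%s': temporal expression '%s' has no normalized value",
                  note$note_id, tes$te_id[missing_val][1]),
          class = "medtimeline_timeline_error")
  }
  if (nrow(tes) == 0) {
    return(structure(list(
      nodes = tibble(node_id = integer(), value = character(),
                     te_ids = list()),
      n_nodes = 0L), class = "mt_timeline"))
  }
  key <- time_sort_key(tes$value)
  ord <- order(key)
  uk <- unique(key[ord])
  nodes <- tibble(
    node_id = as.integer(2L * seq_along(uk) - 1L),
    value = tes$value[ord][match(uk, key[ord])],
    te_ids = lapply(uk, function(k) tes$te_id[key == k])
  )
  structure(list(nodes = nodes, n_nodes = nrow(nodes)), class = "mt_timeline")
}

#' @export
print.mt_timeline <- function(x, ...) {
  cat(sprintf("<mt_timeline> %d nodes, IDs {0..%d}\n", x$n_nodes, 2L * x$n_nodes))
  invisible(x)
}

#' All valid timeline IDs
#'
#' @param timeline An `mt_timeline`.
#' @return Integer vector `0:(2n)` for `n` nodes.
#' @export
timeline_ids <- function(timeline) 0:(2L * timeline$n_nodes)

#' Time node of a temporal expression
#'
#' @param timeline An `mt_timeline`.
#' @param te_id Temporal-expression identifier.
#' @return The odd node ID holding `te_id`.
#' @export
te_node_id <- function(timeline, te_id) {
  hit <- which(vapply(timeline$nodes$te_ids, function(ids) te_id %in% ids,
                      logical(1)))
  if (length(hit) == 0) {
    abort(sprintf("temporal expression '%s' is not on this timeline", te_id),
          class = "medtimeline_timeline_error")
  }
  timeline$nodes$node_id[hit[1]]
}

#' Timeline ID selected by a (temporal expression, relation) pair
#'
#' `SIMULTANEOUS` indexes the expression's own node; `BEFORE` / `AFTER` index
#' the first interval before / after it (node ID minus / plus one). `NONE`
#' never yields an index and raises an error.
#'
#' @param te_id Temporal-expression identifier on `timeline`.
#' @param relation One of `"SIMULTANEOUS"`, `"BEFORE"`, `"AFTER"`.
#' @param timeline An `mt_timeline`.
#' @return Integer timeline ID.
#' @export
relation_to_index <- function(te_id, relation, timeline) {
  node <- te_node_id(timeline, te_id)
  switch(relation,
    SIMULTANEOUS = node,
    BEFORE = node - 1L,
    AFTER = node + 1L,
    abort(sprintf("relation '%s' does not select a timeline index", relation),
          class = "medtimeline_timeline_error")
  )
}

#' Gold relation label for an (entity, temporal expression) pair
#'
#' The label is `SIMULTANEOUS`, `BEFORE` or `AFTER` exactly when the entity's
#' gold index equals the expression's node ID, node ID - 1 or node ID + 1, and
#' `NONE` otherwise. An entity indexed to an interval therefore yields `AFTER`
#' for the node just below it and `BEFORE` for the node just above it: both
#' pairs are positives.
#'
#' @param gold_index The entity's gold timeline ID (must be present).
#' @param te_id Temporal-expression identifier on `timeline`.
#' @param timeline An `mt_timeline`.
#' @return One of the four [relation_classes()].
#' @export
gold_relation_for_pair <- function(gold_index, te_id, timeline) {
  if (is.null(gold_index) || is.na(gold_index)) {
    abort("entity has no gold_index; cannot derive a gold relation",
          class = "medtimeline_timeline_error")
  }
  node <- te_node_id(timeline, te_id)
  if (gold_index == node) "SIMULTANEOUS"
  else if (gold_index == node - 1L) "BEFORE"
  else if (gold_index == node + 1L) "AFTER"
  else "NONE"
}

# numeric sort key for ISO-8601 dates / datetimes (ordering only, no calendar
# arithmetic beyond parsing)
time_sort_key <- function(values) {
  key <- suppressWarnings(as.numeric(as.POSIXct(values, tz = "UTC",
    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d"))))
  if (any(is.na(key))) {
    abort(sprintf("cannot order temporal value '%s' (expected ISO-8601)",
                  values[is.na(key)][1]),
          class = "medtimeline_timeline_error")
  }
  key
}

#' Parse a small set of date surface forms
#'
#' Convenience normalizer for `YYYY-MM-DD`, `YYYY年MM月DD日` and relative
#' `X天前` ("X days ago", resolved against the admission date). Anything else
#' must arrive pre-normalized; full temporal-expression normalization is out
#' of scope.
#'
#' @param surface Date surface string.
#' @param admission_value ISO date the relative forms are resolved against.
#' @return ISO `YYYY-MM-DD` string, or `NA_character_` when unparseable.
#' @export
parse_time_value <- function(surface, admission_value = NULL) {
  s <- trimws(surface)
  m <- stringr::str_match(s, "^(\\d{4})-(\\d{1,2})-(\\d{1,2})$")
  if (!is.na(m[1, 1])) {
    return(sprintf("%04d-%02d-%02d", as.integer(m[1, 2]), as.integer(m[1, 3]),
                   as.integer(m[1, 4])))
  }
  m <- stringr::str_match(s, "^(\\d{4})年(\\d{1,2})月(\\d{1,2})日$")
  if (!is.na(m[1, 1])) {
    return(sprintf("%04d-%02d-%02d", as.integer(m[1, 2]), as.integer(m[1, 3]),
                   as.integer(m[1, 4])))
  }
  m <- stringr::str_match(s, "^(\\d+)天前$")
  if (!is.na(m[1, 1]) && !is.null(admission_value)) {
    d <- as.Date(admission_value) - as.integer(m[1, 2])
    return(format(d, "%Y-%m-%d"))
  }
  NA_character_
}
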