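#' Average class probabilities across models
#'
#' The merged prediction for one pair is the elementwise arithmetic mean of
#' the member models' four-class probability vectors; it stays on the
#' probability simplex and is invariant to the order of its inputs.
#'
#' @param per_model List of numeric probability vectors (length 4, each
#'   summing to 1).
#' @return Numeric probability vector of length 4.
#' @export
merge_probabilities <- function(per_model) {
  stopifnot(length(per_model) >= 1)
  lens <- vapply(per_model, length, integer(1))
  if (any(lens != 4L)) {
    abort("merge_probabilities: all probability vectors must have length 4",
          class = "medtimeline_ensemble_error")
  }
  sums <- vapply(per_model, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-6)) {
    abort("merge_probabilities: inputs must sum to 1",
          class = "medtimeline_ensemble_error")
  }
  Reduce(`+`, per_model) / length(per_model)
}

#' Merge per-pair prediction tables from several classifiers
#'
#' Tibble-level counterpart of [merge_probabilities()]: the tables must cover
#' the same (note, entity, expression) universe; the four probability columns
#' are averaged row-wise.
#'
#' @param predictions List of prediction tibbles as returned by the
#'   `predict()` methods (columns `note_id`, `me_id`, `te_id`, `p_none`,
#'   `p_simultaneous`, `p_before`, `p_after`).
#' @return One merged prediction tibble.
#' @export
merge_predictions <- function(predictions) {
  stopifnot(length(predictions) >= 1)
  key <- function(d) paste(d$note_id, d$me_id, d$te_id)
  base <- predictions[[1]]
  pcols <- c("p_none", "p_simultaneous", "p_before", "p_after")
  acc <- as.matrix(base[, pcols])
  for (d in predictions[-1]) {
    if (!identical(key(d), key(base))) {
      abort("merge_predictions: pair universes differ",
            class = "medtimeline_ensemble_error")
    }
    acc <- acc + as.matrix(d[, pcols])
  }
  base[, pcols] <- acc / length(predictions)
  base
}
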