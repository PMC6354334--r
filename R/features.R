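#' Hand-crafted temporal-relation features for one (entity, expression) pair
#'
#' Computes the ten categorical features used alongside the sentence encoders:
#' \enumerate{
#'   \item section name of the medical entity;
#'   \item section name of the temporal expression;
#'   \item whether both lie in the same section;
#'   \item whether the expression is the admission time, discharge time or
#'     another time;
#'   \item whether any temporal expression lies in the entity's sentence;
#'   \item the number of temporal expressions in the entity's sentence
#'     (`"0"`, `"1"`, `"more"`);
#'   \item whether entity and expression share a sentence;
#'   \item whether the expression is in front of or behind the entity when
#'     they share a sentence (`"na"` otherwise);
#'   \item whether the expression's sentence is in front of, behind, or the
#'     same as the entity's sentence;
#'   \item whether any temporal expression starts in front of the entity
#'     within the entity's section.
#' }
#' "Front" always means the expression span starts before the entity span.
#' All values are categorical strings; extraction is a pure function of the
#' note's spans, sections and sentences.
#'
#' @param me_id,te_id Identifiers of the pair.
#' @param note A [clinical_note()].
#' @param sentences Optional [segment_sentences()] result, recomputed when
#'   `NULL`.
#' @return Named character vector `f1` ... `f10` of class `mt_feature_vector`.
#' @export
extract_relation_features <- function(me_id, te_id, note, sentences = NULL) {
  if (is.null(sentences)) sentences <- segment_sentences(note)
  me <- note$entities[note$entities$me_id == me_id, ]
  te <- note$temporal_expressions[note$temporal_expressions$te_id == te_id, ]
  stopifnot(nrow(me) == 1, nrow(te) == 1)
  tes <- note$temporal_expressions

  me_sec <- section_of_span(note, me$start, me$end)
  te_sec <- section_of_span(note, te$start, te$end)
  me_sent <- sentence_of_span(sentences, me$start, me$end)
  te_sent <- sentence_of_span(sentences, te$start, te$end)
  if (is.na(me_sent) || is.na(te_sent)) {
    abort(sprintf("note '%s': unresolved sentence for pair (%s, %s)",
                  note$note_id, me_id, te_id),
          class = "medtimeline_feature_error")
  }

  sent_of <- function(starts, ends) {
    vapply(seq_along(starts), function(i) {
      sentence_of_span(sentences, starts[i], ends[i])
    }, integer(1))
  }
  te_sents <- sent_of(tes$start, tes$end)
  n_in_me_sent <- sum(te_sents == me_sent, na.rm = TRUE)

  sec_name <- function(i) if (is.na(i)) "Other" else note$sections$name[i]
  same_sentence <- me_sent == te_sent

  me_sec_row <- note$sections[me_sec, ]
  any_front_in_sec <- any(tes$start >= me_sec_row$start &
                            tes$end <= me_sec_row$end &
                            tes$start < me$start)

  fv <- c(
    f1 = sec_name(me_sec),
    f2 = sec_name(te_sec),
    f3 = as.character(identical(me_sec, te_sec)),
    f4 = te$kind,
    f5 = as.character(n_in_me_sent > 0),
    f6 = if (n_in_me_sent == 0) "0" else if (n_in_me_sent == 1) "1" else "more",
    f7 = as.character(same_sentence),
    f8 = if (!same_sentence) "na" else if (te$start < me$start) "front" else "behind",
    f9 = if (te_sent < me_sent) "front" else if (te_sent > me_sent) "behind" else "same",
    f10 = as.character(isTRUE(any_front_in_sec))
  )
  class(fv) <- "mt_feature_vector"
  fv
}

#' @export
print.mt_feature_vector <- function(x, ...) {
  cat("<mt_feature_vector>", paste(names(unclass(x)), unclass(x), sep = "=",
                                   collapse = " "), "\n")
  invisible(x)
}

#' Build per-feature category tables from training pairs
#'
#' Each of the ten features gets a vocabulary of the values seen in training
#' plus a terminal `OTHER` bucket, so prediction-time encoding is total.
#' Tables are serialized with trained models, keeping train- and test-time
#' encodings identical.
#'
#' @param feature_rows List (or tibble rows) of `mt_feature_vector`s.
#' @return Named list of character vectors, one per feature, each ending in
#'   `"OTHER"`.
#' @export
build_feature_tables <- function(feature_rows) {
  mat <- do.call(rbind, lapply(feature_rows, unclass))
  lapply(stats::setNames(seq_len(ncol(mat)), colnames(mat)), function(j) {
    c(sort(unique(mat[, j])), "OTHER")
  })
}

#' One-hot encode a feature vector
#'
#' @param fv An `mt_feature_vector`.
#' @param category_tables Result of [build_feature_tables()].
#' @return List of ten one-hot numeric vectors; unseen values fall into the
#'   `OTHER` position.
#' @export
encode_one_hot <- function(fv, category_tables) {
  vals <- unclass(fv)
  stopifnot(length(vals) == length(category_tables))
  purrr::map2(vals, category_tables, function(v, tab) {
    i <- match(v, tab)
    if (is.na(i)) i <- length(tab)  # OTHER
    out <- numeric(length(tab))
    out[i] <- 1
    out
  })
}

# row index of each feature value in the stacked feature-embedding matrix
feature_row_indices <- function(fv, category_tables) {
  vals <- unclass(fv)
  offs <- c(0, cumsum(vapply(category_tables, length, integer(1))))
  vapply(seq_along(vals), function(i) {
    tab <- category_tables[[i]]
    j <- match(vals[i], tab)
    if (is.na(j)) j <- length(tab)
    offs[i] + j
  }, numeric(1))
}
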