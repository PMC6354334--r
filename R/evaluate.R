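#' Select one timeline index per entity from pair probabilities
#'
#' Over all (candidate expression, relation in SIMULTANEOUS/BEFORE/AFTER)
#' combinations of an entity, the highest probability wins — NONE is never
#' selectable. Ties break towards the smaller character distance between the
#' expression and the entity, then towards candidate order (section anchor
#' first). The chosen (expression, relation) maps to a timeline ID via
#' [relation_to_index()].
#'
#' @param pred_pairs Prediction tibble from a `predict()` method (candidate
#'   pairs plus the four probability columns).
#' @param corpus The `mt_corpus` the pairs came from.
#' @return Tibble with one row per entity: `note_id`, `me_id`, `te_id`,
#'   `relation`, `confidence`, `pred_index`.
#' @export
select_index <- function(pred_pairs, corpus) {
  if (nrow(pred_pairs) == 0) {
    abort("empty candidate set", class = "medtimeline_select_error")
  }
  notes <- stats::setNames(unclass(corpus),
                           vapply(corpus, `[[`, character(1), "note_id"))
  tls <- lapply(notes, build_timeline)
  dist_of <- function(note_id, me_id, te_id) {
    note <- notes[[note_id]]
    me <- note$entities[note$entities$me_id == me_id, ]
    te <- note$temporal_expressions[note$temporal_expressions$te_id == te_id, ]
    abs(te$start - me$start)
  }
  long <- tidyr::pivot_longer(
    pred_pairs,
    cols = c("p_simultaneous", "p_before", "p_after"),
    names_to = "relation", values_to = "prob")
  long$relation <- unname(c(p_simultaneous = "SIMULTANEOUS",
                            p_before = "BEFORE",
                            p_after = "AFTER")[long$relation])
  long$distance <- vapply(seq_len(nrow(long)), function(i) {
    dist_of(long$note_id[i], long$me_id[i], long$te_id[i])
  }, numeric(1))
  picked <- long |>
    dplyr::group_by(.data$note_id, .data$me_id) |>
    dplyr::arrange(dplyr::desc(.data$prob), .data$distance, .data$cand_rank,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  picked$pred_index <- vapply(seq_len(nrow(picked)), function(i) {
    relation_to_index(picked$te_id[i], picked$relation[i],
                      tls[[picked$note_id[i]]])
  }, integer(1))
  dplyr::select(picked, "note_id", "me_id", "te_id", "relation",
                confidence = "prob", "pred_index")
}

# predicted label per pair = argmax over all four classes
predicted_relations <- function(pred_pairs) {
  pcols <- c("p_none", "p_simultaneous", "p_before", "p_after")
  idx <- max.col(as.matrix(pred_pairs[, pcols]), ties.method = "first")
  pred_pairs$pred_relation <- relation_classes()[idx]
  pred_pairs
}

#' Micro-averaged precision/recall/F1 for relation classification
#'
#' Positives are the non-NONE pairs. A pair counts as correct only when the
#' predicted label equals the gold label; precision divides by predicted
#' positives, recall by gold positives, and 0/0 is defined as 0.
#'
#' @param gold Tibble with columns `note_id`, `me_id`, `te_id`, `relation`
#'   (gold labels over the pair universe).
#' @param predicted Same universe with predicted `relation` labels.
#' @return List with `precision`, `recall`, `f1`.
#' @export
relation_prf <- function(gold, predicted) {
  kg <- paste(gold$note_id, gold$me_id, gold$te_id)
  kp <- paste(predicted$note_id, predicted$me_id, predicted$te_id)
  if (!identical(sort(kg), sort(kp))) {
    abort("relation_prf: gold and predicted pair universes differ",
          class = "medtimeline_eval_error")
  }
  g <- gold$relation[order(kg)]
  p <- predicted$relation[order(kp)]
  n_pred_pos <- sum(p != "NONE")
  n_gold_pos <- sum(g != "NONE")
  n_correct <- sum(p != "NONE" & p == g)
  prec <- if (n_pred_pos == 0) 0 else n_correct / n_pred_pos
  rec <- if (n_gold_pos == 0) 0 else n_correct / n_gold_pos
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1)
}

# gold entity table with node flags + chosen-TE node, shared by the metrics
eval_frame <- function(corpus, predictions) {
  if (!inherits(corpus, "mt_corpus")) corpus <- new_corpus(corpus)
  notes <- stats::setNames(unclass(corpus),
                           vapply(corpus, `[[`, character(1), "note_id"))
  tls <- lapply(notes, build_timeline)
  gold <- as_tibble(corpus)[, c("note_id", "me_id", "gold_index")]
  if (any(is.na(gold$gold_index))) {
    abort("evaluation corpus has entities without gold indices",
          class = "medtimeline_eval_error")
  }
  d <- dplyr::left_join(gold, predictions, by = c("note_id", "me_id"))
  if (any(is.na(d$pred_index))) {
    warn(sprintf("%d entities have no prediction; counted as wrong",
                 sum(is.na(d$pred_index))))
  }
  d$te_node <- vapply(seq_len(nrow(d)), function(i) {
    if (is.na(d$pred_index[i])) return(NA_integer_)
    te_node_id(tls[[d$note_id[i]]], d$te_id[i])
  }, integer(1))
  d$strict <- !is.na(d$pred_index) & d$pred_index == d$gold_index
  gold_is_node <- d$gold_index %% 2L == 1L
  te_ok <- !is.na(d$te_node) &
    ((gold_is_node & d$te_node == d$gold_index) |
       (!gold_is_node & abs(d$te_node - d$gold_index) == 1L))
  d$relaxed <- d$strict | te_ok
  d$gold_is_node <- gold_is_node
  d
}

#' Relaxed and strict indexing accuracy
#'
#' Strict: the predicted timeline ID equals the gold one (correct expression
#' and correct relation type). Relaxed: the chosen expression is right — it
#' sits on the gold node, or is adjacent to the gold interval — regardless of
#' the relation type. Strict is the primary criterion and never exceeds
#' relaxed.
#'
#' @param corpus `mt_corpus` with gold indices.
#' @param predictions Index-prediction tibble ([select_index()] or
#'   [rule_based_index()] output).
#' @return List with `relaxed`, `strict`, `n`.
#' @export
indexing_accuracy <- function(corpus, predictions) {
  d <- eval_frame(corpus, predictions)
  list(relaxed = mean(d$relaxed), strict = mean(d$strict), n = nrow(d))
}

#' Precision/recall/F1 split by time node vs time interval
#'
#' An entity predicted to an odd ID counts towards node predictions, to an
#' even ID towards interval predictions; only strictly correct predictions
#' count as hits. Recall divides by the gold node (interval) entities.
#'
#' @inheritParams indexing_accuracy
#' @return List with `node` and `interval`, each `precision`/`recall`/`f1`.
#' @export
breakdown_by_kind <- function(corpus, predictions) {
  d <- eval_frame(corpus, predictions)
  one <- function(node_side) {
    pred_side <- !is.na(d$pred_index) & (d$pred_index %% 2L == 1L) == node_side
    gold_side <- d$gold_is_node == node_side
    hits <- sum(d$strict & pred_side)
    prec <- if (sum(pred_side) == 0) 0 else hits / sum(pred_side)
    rec <- if (sum(gold_side) == 0) 0 else hits / sum(gold_side)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    list(precision = prec, recall = rec, f1 = f1)
  }
  list(node = one(TRUE), interval = one(FALSE))
}

#' Selection-error and type-error counts
#'
#' Strict errors split into two kinds: a *type error* chose the right
#' expression (the relaxed condition holds) but the wrong relation; a
#' *selection error* chose a wrong expression outright. The two counts
#' partition the strict errors.
#'
#' @inheritParams indexing_accuracy
#' @return List with `selection_errors`, `type_errors`, `strict_errors`.
#' @export
error_taxonomy <- function(corpus, predictions) {
  d <- eval_frame(corpus, predictions)
  wrong <- !d$strict
  type_err <- wrong & d$relaxed
  list(selection_errors = sum(wrong & !d$relaxed),
       type_errors = sum(type_err),
       strict_errors = sum(wrong))
}

#' Full evaluation report
#'
#' Bundles relation micro-P/R/F1 (when pair-level predictions are supplied),
#' relaxed/strict indexing accuracy, the node/interval breakdown, and the
#' error taxonomy into one report object with `print()`, `tidy()`,
#' `glance()` and `autoplot()` methods.
#'
#' @param corpus Evaluation `mt_corpus` with gold indices.
#' @param predictions Index predictions ([select_index()] /
#'   [rule_based_index()] output).
#' @param pred_pairs Optional pair-level prediction tibble with probability
#'   columns; enables the relation P/R/F1 block.
#' @param method Optional method label carried into the report.
#' @return An `mt_eval_report`.
#' @export
evaluate_indexing <- function(corpus, predictions, pred_pairs = NULL,
                              method = NA_character_) {
  acc <- indexing_accuracy(corpus, predictions)
  rel <- NULL
  if (!is.null(pred_pairs)) {
    pp <- predicted_relations(pred_pairs)
    gold <- pp[, c("note_id", "me_id", "te_id")]
    gold$relation <- pp$gold_relation
    pred <- pp[, c("note_id", "me_id", "te_id")]
    pred$relation <- pp$pred_relation
    rel <- relation_prf(gold, pred)
  }
  structure(list(
    method = method,
    relation = rel,
    relaxed = acc$relaxed, strict = acc$strict, n = acc$n,
    by_kind = breakdown_by_kind(corpus, predictions),
    errors = error_taxonomy(corpus, predictions)
  ), class = "mt_eval_report")
}

#' @export
print.mt_eval_report <- function(x, ...) {
  cat(sprintf("Temporal indexing evaluation%s (%d entities)\n",
              if (is.na(x$method)) "" else paste0(" - ", x$method), x$n))
  if (!is.null(x$relation)) {
    cat(sprintf("  relation      P %6.2f%%  R %6.2f%%  F1 %6.2f%%\n",
                100 * x$relation$precision, 100 * x$relation$recall,
                100 * x$relation$f1))
  }
  cat(sprintf("  indexing      relaxed %6.2f%%  strict %6.2f%%\n",
              100 * x$relaxed, 100 * x$strict))
  for (kind in c("node", "interval")) {
    b <- x$by_kind[[kind]]
    cat(sprintf("  %-13s P %6.2f%%  R %6.2f%%  F1 %6.2f%%\n", kind,
                100 * b$precision, 100 * b$recall, 100 * b$f1))
  }
  cat(sprintf("  errors        selection %d  type %d\n",
              x$errors$selection_errors, x$errors$type_errors))
  invisible(x)
}

#' @export
tidy.mt_eval_report <- function(x, ...) {
  tibble(
    method = x$method,
    relation_precision = x$relation$precision %||% NA_real_,
    relation_recall = x$relation$recall %||% NA_real_,
    relation_f1 = x$relation$f1 %||% NA_real_,
    relaxed = x$relaxed, strict = x$strict,
    node_precision = x$by_kind$node$precision,
    node_recall = x$by_kind$node$recall,
    node_f1 = x$by_kind$node$f1,
    interval_precision = x$by_kind$interval$precision,
    interval_recall = x$by_kind$interval$recall,
    interval_f1 = x$by_kind$interval$f1,
    selection_errors = x$errors$selection_errors,
    type_errors = x$errors$type_errors,
    n_entities = x$n
  )
}

#' @export
glance.mt_eval_report <- function(x, ...) {
  tibble(method = x$method, strict = x$strict, relaxed = x$relaxed,
         relation_f1 = x$relation$f1 %||% NA_real_, n_entities = x$n)
}

#' @export
autoplot.mt_eval_report <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::select("relaxed", "strict", "node_f1", "interval_f1") |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Temporal indexing metrics")
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `mt_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
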