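#' Train one of the indexing methods on a corpus
#'
#' Dispatches to the rule engine (no training), the SVM baseline, one of the
#' neural variants, or the merged ensemble (which trains the SVM and all
#' three neural variants and averages their probabilities at prediction
#' time).
#'
#' @param corpus Training `mt_corpus` with gold indices.
#' @param method One of `"rule"`, `"svm"`, `"cnn"`, `"rnn"`, `"rnn-cnn"`,
#'   `"merged"`.
#' @param config A [model_config()] for the neural variants (its `variant`
#'   field is overridden by `method`).
#' @param seed Seed forwarded to the neural trainers.
#' @param ... Passed on to [train_svm_model()] for the SVM.
#' @return An `mt_indexer`: method tag plus whatever fitted models it needs.
#' @export
train_indexer <- function(corpus, method = c("rnn-cnn", "cnn", "rnn", "svm",
                                             "rule", "merged"),
                          config = model_config(), seed = 1L, ...) {
  method <- match.arg(method)
  fit_neural <- function(variant, seed_offset = 0L) {
    cfg <- config
    cfg$variant <- variant
    train_relation_model(corpus, cfg, seed = seed + seed_offset)
  }
  models <- switch(method,
    rule = list(),
    svm = list(svm = train_svm_model(corpus, ...)),
    cnn = list(cnn = fit_neural("cnn")),
    rnn = list(rnn = fit_neural("rnn")),
    `rnn-cnn` = list(`rnn-cnn` = fit_neural("rnn-cnn")),
    merged = list(
      svm = train_svm_model(corpus, ...),
      cnn = fit_neural("cnn", 1L),
      rnn = fit_neural("rnn", 2L),
      `rnn-cnn` = fit_neural("rnn-cnn", 3L)
    )
  )
  structure(list(method = method, models = models), class = "mt_indexer")
}

#' @export
print.mt_indexer <- function(x, ...) {
  cat(sprintf("<mt_indexer %s>%s\n", x$method,
              if (length(x$models)) paste0(" members: ",
                                           paste(names(x$models), collapse = ", "))
              else ""))
  invisible(x)
}

#' Index every entity of a corpus with a fitted indexer
#'
#' For probability-based methods this predicts the four-class probabilities
#' of every candidate pair (averaging members for `"merged"`) and selects the
#' highest-confidence (expression, relation) per entity; the rule method
#' applies its ordered rules directly.
#'
#' @param indexer An `mt_indexer` from [train_indexer()].
#' @param corpus An `mt_corpus`.
#' @return List with `predictions` (entity-level index tibble) and
#'   `pred_pairs` (pair-level probabilities, `NULL` for the rule method).
#' @export
index_corpus <- function(indexer, corpus) {
  if (indexer$method == "rule") {
    return(list(predictions = rule_based_index(corpus), pred_pairs = NULL))
  }
  pairs <- candidate_pairs(corpus)
  preds <- lapply(indexer$models, function(m) predict(m, corpus, pairs = pairs))
  pp <- if (length(preds) == 1) preds[[1]] else merge_predictions(unname(preds))
  list(predictions = select_index(pp, corpus), pred_pairs = pp)
}

#' Train, index and evaluate in one call
#'
#' @param train_corpus,test_corpus Training and evaluation corpora with gold
#'   indices.
#' @param method Indexing method, see [train_indexer()].
#' @param config A [model_config()].
#' @param seed Training seed.
#' @param ... Passed to [train_indexer()].
#' @return An `mt_eval_report` for `test_corpus`, with the fitted indexer in
#'   `attr(., "indexer")` and the predictions in `attr(., "predictions")`.
#' @export
run_indexing_experiment <- function(train_corpus, test_corpus,
                                    method = "rnn-cnn",
                                    config = model_config(), seed = 1L, ...) {
  indexer <- train_indexer(train_corpus, method, config, seed, ...)
  out <- index_corpus(indexer, test_corpus)
  report <- evaluate_indexing(test_corpus, out$predictions, out$pred_pairs,
                              method = method)
  attr(report, "indexer") <- indexer
  attr(report, "predictions") <- out$predictions
  report
}
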