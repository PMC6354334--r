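#' Train a neural relation classifier
#'
#' Builds the candidate-pair instance set of the corpus (gold labels derived
#' from gold indices), fits the vocabulary and feature category tables on it,
#' and trains the selected network variant by mini-batch stochastic gradient
#' descent on the mean cross-entropy, with dropout on the fused
#' representation. With a fixed `seed` the whole run — initialization,
#' shuffling, dropout — is reproducible bit for bit on one platform.
#'
#' @param corpus Training `mt_corpus` with gold indices.
#' @param config A [model_config()]; `config$variant` picks `"rnn-cnn"`,
#'   `"cnn"` or `"rnn"`.
#' @param embeddings Optional word2vec table from [read_word2vec()] used to
#'   initialize the word-embedding matrix.
#' @param seed Integer seed for the run (default 1).
#' @param verbose Print per-epoch mean loss.
#' @return An `mt_relation_model`: configuration, vocabulary, feature
#'   category tables, parameters, and a per-epoch `loss_log` tibble.
#' @export
train_relation_model <- function(corpus, config = model_config(),
                                 embeddings = NULL, seed = 1L,
                                 verbose = FALSE) {
  pairs <- candidate_pairs(corpus)
  if (nrow(pairs) == 0) abort("corpus yields no candidate pairs")
  if (any(is.na(pairs$gold_relation))) {
    abort("training corpus has entities without gold indices")
  }
  bad <- setdiff(unique(pairs$gold_relation), relation_classes())
  if (length(bad)) abort(sprintf("unknown relation label '%s'", bad[1]))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  enc <- pair_sentence_encodings(pairs, corpus, config$max_len)
  vocab <- build_vocab(enc)
  enc$me <- resolve_ids(enc$me, vocab, config)
  enc$te <- resolve_ids(enc$te, vocab, config)
  feature_tables <- build_feature_tables(enc$features)
  params <- init_relation_params(config, vocab, feature_tables, embeddings)
  y <- match(pairs$gold_relation, relation_classes())
  zrows <- vapply(enc$features, feature_row_indices, numeric(10),
                  category_tables = feature_tables)  # 10 x N

  if (verbose) {
    message(sprintf("training %s: %d pairs, vocab %d, lr %.3g, %d epochs",
                    config$variant, nrow(pairs), length(vocab),
                    config$learning_rate, config$epochs))
  }

  N <- nrow(pairs)
  bs <- config$batch_size
  lens <- vapply(seq_len(N), function(i) {
    max(length(enc$me[[i]]$tokens), length(enc$te[[i]]$tokens))
  }, integer(1))
  loss_log <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(N)
    # length-bucketed shuffling: sort within chunks of 8 batches so padding
    # stays tight while batch composition still varies between epochs
    chunk <- 8L * bs
    ord <- unlist(lapply(split(ord, ceiling(seq_along(ord) / chunk)),
                         function(ix) ix[order(lens[ix])]), use.names = FALSE)
    batch_starts <- seq(1L, N, by = bs)
    total_loss <- 0
    for (s in batch_starts) {
      idx <- ord[s:min(s + bs - 1L, N)]
      batch <- list(
        me = batch_side(enc$me, idx, vocab, config),
        te = batch_side(enc$te, idx, vocab, config),
        zrows = zrows[, idx, drop = FALSE],
        y = y[idx]
      )
      out <- nn_batch(params, config, batch, train = TRUE, compute_grads = TRUE)
      params <- sgd_step(params, out$grads, config$learning_rate)
      total_loss <- total_loss + out$loss * length(idx)
    }
    loss_log[epoch] <- total_loss / N
    if (verbose) message(sprintf("  epoch %2d  mean loss %.4f", epoch, loss_log[epoch]))
  }

  # out-of-vocabulary tokens map to [UNK], whose vector is the mean of all
  # trained word vectors
  params$Ew[, 2L] <- rowMeans(params$Ew[, -(1:2), drop = FALSE])

  structure(list(
    config = config, vocab = vocab, feature_tables = feature_tables,
    params = params,
    loss_log = tibble(epoch = seq_len(config$epochs), loss = loss_log),
    classes = relation_classes()
  ), class = "mt_relation_model")
}

#' @export
print.mt_relation_model <- function(x, ...) {
  cat(sprintf("<mt_relation_model %s> vocab %d, %d feature categories, final loss %.4f\n",
              x$config$variant, length(x$vocab),
              sum(vapply(x$feature_tables, length, integer(1))),
              utils::tail(x$loss_log$loss, 1)))
  invisible(x)
}

#' @describeIn train_relation_model per-epoch training loss, one row per epoch.
#' @param x,object An `mt_relation_model`.
#' @param ... Unused.
#' @export
tidy.mt_relation_model <- function(x, ...) x$loss_log

#' @describeIn train_relation_model one-row model summary.
#' @export
glance.mt_relation_model <- function(x, ...) {
  tibble(variant = x$config$variant, vocab_size = length(x$vocab),
         epochs = x$config$epochs,
         final_loss = utils::tail(x$loss_log$loss, 1))
}

#' @describeIn train_relation_model training-loss curve.
#' @export
autoplot.mt_relation_model <- function(object, ...) {
  ggplot2::ggplot(object$loss_log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy",
                  title = sprintf("Training loss (%s)", object$config$variant))
}

#' Predict relation probabilities for candidate pairs
#'
#' Runs the trained network over every candidate pair of `corpus` in
#' evaluation mode (no dropout) and returns the four class probabilities per
#' pair.
#'
#' @param object An `mt_relation_model`.
#' @param corpus An `mt_corpus`.
#' @param pairs Optional pre-computed [candidate_pairs()] tibble.
#' @param ... Unused.
#' @return The pairs tibble with columns `p_none`, `p_simultaneous`,
#'   `p_before`, `p_after` appended.
#' @export
predict.mt_relation_model <- function(object, corpus, pairs = NULL, ...) {
  cfg <- object$config
  if (is.null(pairs)) pairs <- candidate_pairs(corpus)
  enc <- pair_sentence_encodings(pairs, corpus, cfg$max_len)
  enc$me <- resolve_ids(enc$me, object$vocab, cfg)
  enc$te <- resolve_ids(enc$te, object$vocab, cfg)
  zrows <- vapply(enc$features, feature_row_indices, numeric(10),
                  category_tables = object$feature_tables)
  N <- nrow(pairs)
  probs <- matrix(0, 4L, N)
  ord <- order(vapply(seq_len(N), function(i) {
    max(length(enc$me[[i]]$tokens), length(enc$te[[i]]$tokens))
  }, integer(1)))
  bs <- cfg$batch_size
  for (s in seq(1L, N, by = bs)) {
    idx <- ord[s:min(s + bs - 1L, N)]
    batch <- list(
      me = batch_side(enc$me, idx, object$vocab, cfg),
      te = batch_side(enc$te, idx, object$vocab, cfg),
      zrows = zrows[, idx, drop = FALSE], y = NULL
    )
    probs[, idx] <- nn_batch(object$params, cfg, batch, train = FALSE)$probs
  }
  pairs$p_none <- probs[1, ]
  pairs$p_simultaneous <- probs[2, ]
  pairs$p_before <- probs[3, ]
  pairs$p_after <- probs[4, ]
  pairs
}

#' Classify a single (entity, expression) pair
#'
#' Convenience single-instance wrapper around the batched network.
#'
#' @param model An `mt_relation_model`.
#' @param me_encoding,te_encoding Sentence encodings as produced by
#'   [encode_input()] (lists with `tokens`, `k`).
#' @param fv An `mt_feature_vector` from [extract_relation_features()].
#' @return Named probability vector over [relation_classes()].
#' @export
classify_pair <- function(model, me_encoding, te_encoding, fv) {
  cfg <- model$config
  prep <- function(e) {
    w <- window_and_positions(e$tokens, e$k, cfg$max_len)
    list(w)
  }
  encs <- list(me = prep(me_encoding), te = prep(te_encoding))
  zr <- matrix(feature_row_indices(fv, model$feature_tables), ncol = 1)
  batch <- list(
    me = batch_side(encs$me, 1L, model$vocab, cfg),
    te = batch_side(encs$te, 1L, model$vocab, cfg),
    zrows = zr, y = NULL
  )
  p <- nn_batch(model$params, cfg, batch, train = FALSE)$probs[, 1]
  stats::setNames(as.numeric(p), relation_classes())
}

#' Save / load a trained relation model
#'
#' The bundle is a directory holding the parameter tensors in an RDS
#' container plus JSON sidecars for the vocabulary, feature category tables
#' and configuration; loading restores bit-identical predictions.
#'
#' @param model An `mt_relation_model`.
#' @param dir Bundle directory (created if needed).
#' @return `dir` (save) or the restored model (load).
#' @export
save_relation_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  jsonlite::write_json(
    list(config = unclass(model$config), vocab = model$vocab,
         feature_tables = model$feature_tables, classes = model$classes,
         loss = model$loss_log$loss),
    file.path(dir, "model.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' @rdname save_relation_model
#' @export
load_relation_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- do.call(model_config, meta$config[c(
    "word_dim", "pos_dim", "feat_dim", "lstm_units", "conv_widths",
    "conv_filters", "max_len", "dropout", "batch_size", "epochs",
    "learning_rate", "variant")])
  structure(list(
    config = cfg, vocab = meta$vocab,
    feature_tables = lapply(meta$feature_tables, as.character),
    params = readRDS(file.path(dir, "params.rds")),
    loss_log = tibble(epoch = seq_along(meta$loss), loss = meta$loss),
    classes = meta$classes
  ), class = "mt_relation_model")
}
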