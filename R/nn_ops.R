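# Exported single-instance layer operations. These are the building blocks
# the batched trainer composes; exposing them keeps every layer directly
# testable against independent oracles.

#' Encode a tokenized sentence into the input representation
#'
#' Looks up the word vector and the position vector of every token and
#' concatenates them: row `t` is `[E_w[w_t], E_d[t - k]]` for target index
#' `k`. Sentences longer than `max_len` are truncated to a window centred on
#' the target; offsets are clipped to the embedded range.
#'
#' @param tokens Character vector of tokens (target span collapsed to one
#'   token).
#' @param target 1-based index of the target token.
#' @param model An `mt_relation_model` (or any list with `params$Ew`,
#'   `params$Ed`, `vocab` and `config`).
#' @return List of class `mt_sentence_encoding`: `tokens`, `k`, `positions`,
#'   and `X` (n-by-(word_dim + pos_dim) matrix).
#' @export
encode_input <- function(tokens, target, model) {
  if (length(tokens) == 0) {
    abort("empty token sequence", class = "medtimeline_nn_error")
  }
  cfg <- model$config
  stopifnot(target >= 1, target <= length(tokens))
  w <- window_and_positions(tokens, as.integer(target), cfg$max_len)
  ids <- token_ids(w$tokens, model$vocab)
  pidx <- pos_index(w$positions, cfg$max_len)
  X <- t(rbind(model$params$Ew[, ids, drop = FALSE],
               model$params$Ed[, pidx, drop = FALSE]))
  structure(list(tokens = w$tokens, k = w$k, positions = w$positions, X = X),
            class = "mt_sentence_encoding")
}

#' Embed one-hot relation features
#'
#' Each one-hot vector selects one column of the feature-embedding matrix;
#' the ten embedded features are concatenated into the representation `Z`.
#'
#' @param one_hots List of one-hot vectors from [encode_one_hot()] (their
#'   lengths must sum to the number of columns of `Eg`).
#' @param Eg Feature-embedding matrix (`feat_dim` rows, one column per
#'   category across all features).
#' @return Numeric vector of length `length(one_hots) * nrow(Eg)`.
#' @export
embed_features <- function(one_hots, Eg) {
  sizes <- vapply(one_hots, length, integer(1))
  if (sum(sizes) != ncol(Eg)) {
    abort(sprintf("one-hot widths sum to %d but Eg has %d categories",
                  sum(sizes), ncol(Eg)), class = "medtimeline_nn_error")
  }
  offs <- c(0L, cumsum(sizes))
  unlist(lapply(seq_along(one_hots), function(i) {
    g <- one_hots[[i]]
    stopifnot(sum(g == 1) == 1, all(g %in% c(0, 1)))
    Eg[, offs[i] + which(g == 1)]
  }))
}

#' Run a (bidirectional) peephole LSTM over a representation sequence
#'
#' Applies the gated recurrence with peephole connections — the input and
#' forget gates see the previous cell state, the output gate the current one
#' — forward and, when `params_b` is given, backward over the sequence,
#' concatenating both directions per step. Initial hidden and cell states are
#' zero; masked (padding) steps carry the state through unchanged.
#'
#' @param X n-by-d matrix, one row per step.
#' @param params_f Forward-direction parameters: list with `Wx` (4h x d),
#'   `Wh` (4h x h), peepholes `Pi`, `Pf`, `Po` (h x h) and bias `b` (4h);
#'   gate order input / forget / candidate / output.
#' @param params_b Optional backward-direction parameters; `NULL` for a
#'   unidirectional pass.
#' @param mask Optional 0/1 vector of length n (1 = real token).
#' @return n-by-h (or n-by-2h when bidirectional) matrix `H`.
#' @export
lstm_sequence <- function(X, params_f, params_b = NULL, mask = NULL) {
  n <- nrow(X)
  if (ncol(params_f$Wx) != ncol(X)) {
    abort("lstm_sequence: input width does not match parameters",
          class = "medtimeline_nn_error")
  }
  if (is.null(mask)) mask <- rep(1, n)
  Xc <- array(t(X), c(ncol(X), 1L, n))
  m <- matrix(mask, 1L, n)
  f <- .lstm_forward_cpp(Xc, m, params_f$Wx, params_f$Wh, params_f$Pi,
                         params_f$Pf, params_f$Po, params_f$b, FALSE)
  Hf <- t(matrix(f$H, nrow = dim(f$H)[1]))
  if (is.null(params_b)) return(Hf)
  b <- .lstm_forward_cpp(Xc, m, params_b$Wx, params_b$Wh, params_b$Pi,
                         params_b$Pf, params_b$Po, params_b$b, TRUE)
  Hb <- t(matrix(b$H, nrow = dim(b$H)[1]))
  cbind(Hf, Hb)
}

#' Multi-width convolution with max-pooling over a sentence
#'
#' For every filter of width `k`, slides over the `n - k + 1` windows of the
#' sequence, applies the sigmoid of the filter response, and keeps the
#' maximum — windows lying entirely in padding are excluded. The pooled
#' values of all filters across all widths concatenate into the sentence
#' representation `C`.
#'
#' @param H n-by-D matrix (LSTM output, or the raw input representations for
#'   the CNN-only variant).
#' @param bank List with `W` (list of filter matrices, one per width, each
#'   `n_filters x (k*D)`), `b` (list of bias vectors) and `widths`.
#' @param n_real Number of real (non-padding) rows of `H`; defaults to all.
#' @return Numeric vector of pooled features, length `sum(filters)`.
#' @export
conv_maxpool <- function(H, bank, n_real = nrow(H)) {
  Hc <- array(t(H), c(ncol(H), 1L, nrow(H)))
  out <- .conv_forward_cpp(Hc, as.integer(n_real), bank$W, bank$b,
                           as.integer(bank$widths))
  as.numeric(out$C)
}

#' Read word embeddings in word2vec text format
#'
#' Header line "V D" followed by one token and D floats per line.
#'
#' @param path Path to the text-format embedding file.
#' @return List with `vocab` (character) and `vectors` (D x V matrix).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || any(is.na(hdr))) {
    abort("word2vec file: malformed header (expected 'V D')",
          class = "medtimeline_parse_error")
  }
  V <- hdr[1]; D <- hdr[2]
  body <- lines[1 + seq_len(V)]
  parts <- strsplit(body, "\\s+")
  vocab <- vapply(parts, `[[`, character(1), 1)
  vectors <- vapply(parts, function(p) as.numeric(p[2:(D + 1)]), numeric(D))
  if (any(is.na(vectors))) {
    abort("word2vec file: non-numeric vector entries",
          class = "medtimeline_parse_error")
  }
  list(vocab = vocab, vectors = matrix(vectors, nrow = D))
}
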