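#' Hyper-parameter configuration for the neural relation classifiers
#'
#' Defaults follow the published configuration: 50-dimensional word
#' representations, 30-dimensional position representations, 20-dimensional
#' feature representations, LSTM units of size 50 per direction, convolution
#' filters of widths 3/5/7 with 100 filters in total, sentences capped at 100
#' tokens, dropout 0.5, mini-batches of 32 and 20 training epochs. The
#' learning rate is not part of that table; the package default is a constant
#' 0.1 with plain SGD, and it is logged at the start of every training run.
#'
#' @param word_dim,pos_dim,feat_dim Embedding dimensions.
#' @param lstm_units Hidden units per LSTM direction.
#' @param conv_widths Filter (context window) widths.
#' @param conv_filters Total number of convolution filters, split as evenly
#'   as possible across the widths.
#' @param max_len Maximum sentence length in tokens; longer sentences are
#'   truncated to a window centred on the target, shorter ones padded.
#' @param dropout Dropout probability on the fused representation
#'   `[C_M, C_T, Z]` before the output layer (training only).
#' @param batch_size,epochs,learning_rate SGD settings.
#' @param variant `"rnn-cnn"` (LSTM then convolution), `"cnn"` (convolution
#'   directly on the word representations) or `"rnn"` (final forward and
#'   backward LSTM states as the sentence representation).
#' @return A list of class `mt_model_config`.
#' @export
model_config <- function(word_dim = 50L, pos_dim = 30L, feat_dim = 20L,
                         lstm_units = 50L, conv_widths = c(3L, 5L, 7L),
                         conv_filters = 100L, max_len = 100L, dropout = 0.5,
                         batch_size = 32L, epochs = 20L, learning_rate = 0.1,
                         variant = c("rnn-cnn", "cnn", "rnn")) {
  variant <- match.arg(variant)
  nw <- length(conv_widths)
  per <- rep(conv_filters %/% nw, nw)
  extra <- conv_filters %% nw
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  structure(list(
    word_dim = as.integer(word_dim), pos_dim = as.integer(pos_dim),
    feat_dim = as.integer(feat_dim), lstm_units = as.integer(lstm_units),
    conv_widths = as.integer(conv_widths),
    conv_filters = as.integer(conv_filters),
    filters_per_width = as.integer(per),
    max_len = as.integer(max_len), dropout = dropout,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    learning_rate = learning_rate, variant = variant
  ), class = "mt_model_config")
}

#' @export
print.mt_model_config <- function(x, ...) {
  cat("<mt_model_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = "/")))
  invisible(x)
}

# representation width entering the output layer for one sentence
rep_dim <- function(cfg) {
  if (cfg$variant == "rnn") 2L * cfg$lstm_units else sum(cfg$filters_per_width)
}

conv_input_dim <- function(cfg) {
  if (cfg$variant == "cnn") cfg$word_dim + cfg$pos_dim else 2L * cfg$lstm_units
}

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

unif1 <- function(nr, nc) matrix(stats::runif(nr * nc, -1, 1), nr, nc)

init_lstm_params <- function(d, h) {
  list(Wx = glorot(4L * h, d), Wh = glorot(4L * h, h),
       Pi = glorot(h, h), Pf = glorot(h, h), Po = glorot(h, h),
       b = numeric(4L * h))
}

# embedding matrices are stored dimension-by-rows (one column per vocabulary
# item) for cheap column gathering; E_d rows cover clipped offsets
# -(max_len-1) .. +(max_len-1) plus a PAD column, E_g covers all feature
# categories (incl. per-feature OTHER buckets)
init_relation_params <- function(cfg, vocab, feature_tables,
                                 embeddings = NULL) {
  V <- length(vocab)
  P <- 2L * cfg$max_len            # offsets + PAD column at index 2*max_len
  G <- sum(vapply(feature_tables, length, integer(1)))
  Ew <- unif1(cfg$word_dim, V)
  if (!is.null(embeddings)) {
    hit <- match(vocab, embeddings$vocab)
    ok <- !is.na(hit)
    if (nrow(embeddings$vectors) != cfg$word_dim) {
      abort("embedding dimension does not match word_dim")
    }
    Ew[, ok] <- embeddings$vectors[, hit[ok], drop = FALSE]
  }
  d <- cfg$word_dim + cfg$pos_dim
  h <- cfg$lstm_units
  params <- list(
    Ew = Ew,
    Ed = unif1(cfg$pos_dim, P),
    Eg = unif1(cfg$feat_dim, G)
  )
  if (cfg$variant != "cnn") {
    params$lstm_f <- init_lstm_params(d, h)
    params$lstm_b <- init_lstm_params(d, h)
  }
  if (cfg$variant != "rnn") {
    D <- conv_input_dim(cfg)
    wnames <- paste0("w", cfg$conv_widths)
    params$conv <- list(
      W = stats::setNames(purrr::map2(cfg$filters_per_width, cfg$conv_widths,
                                      function(nf, k) glorot(nf, k * D)), wnames),
      b = stats::setNames(lapply(cfg$filters_per_width, numeric), wnames)
    )
  }
  fused <- 2L * rep_dim(cfg) + 10L * cfg$feat_dim
  params$Wo <- glorot(4L, fused)
  params$bo <- numeric(4L)
  params
}

# position index in E_d for a clipped signed offset
pos_index <- function(offsets, max_len) offsets + max_len

# ---------------------------------------------------------------------------
# batched tensors

# resolve token / position ids once per encoding set
resolve_ids <- function(encodings, vocab, cfg) {
  lapply(encodings, function(e) {
    e$ids <- token_ids(e$tokens, vocab)
    e$pidx <- pos_index(e$positions, cfg$max_len)
    e
  })
}

# batch side: tok/pos/mask are (B x n) matrices, nvalid counts real tokens
batch_side <- function(encodings, idx, vocab, cfg) {
  lens <- vapply(idx, function(i) length(encodings[[i]]$tokens), integer(1))
  n <- max(max(lens), max(cfg$conv_widths))
  B <- length(idx)
  tok <- matrix(1L, B, n)                      # [PAD]
  pos <- matrix(2L * cfg$max_len, B, n)        # PAD position column
  mask <- matrix(0, B, n)
  for (b in seq_len(B)) {
    e <- encodings[[idx[b]]]
    m <- lens[b]
    tok[b, seq_len(m)] <- e$ids %||% token_ids(e$tokens, vocab)
    pos[b, seq_len(m)] <- e$pidx %||% pos_index(e$positions, cfg$max_len)
    mask[b, seq_len(m)] <- 1
  }
  list(tok = tok, pos = pos, mask = mask, nvalid = lens, n = n)
}

embed_side <- function(params, cfg, side) {
  B <- nrow(side$tok); n <- ncol(side$tok)
  d <- cfg$word_dim + cfg$pos_dim
  X <- array(0, c(d, B, n))
  tok_vec <- as.vector(side$tok)   # column-major: b fastest, then t
  pos_vec <- as.vector(side$pos)
  X[seq_len(cfg$word_dim), , ] <- params$Ew[, tok_vec]
  X[cfg$word_dim + seq_len(cfg$pos_dim), , ] <- params$Ed[, pos_vec]
  X
}

# forward one sentence side; returns representation (rep_dim x B) and cache
forward_side <- function(params, cfg, side) {
  X <- embed_side(params, cfg, side)
  cache <- list(X = X, side = side)
  if (cfg$variant != "cnn") {
    f <- .lstm_forward_cpp(X, side$mask, params$lstm_f$Wx, params$lstm_f$Wh,
                           params$lstm_f$Pi, params$lstm_f$Pf, params$lstm_f$Po,
                           params$lstm_f$b, FALSE)
    b <- .lstm_forward_cpp(X, side$mask, params$lstm_b$Wx, params$lstm_b$Wh,
                           params$lstm_b$Pi, params$lstm_b$Pf, params$lstm_b$Po,
                           params$lstm_b$b, TRUE)
    h <- cfg$lstm_units
    B <- dim(X)[2]; n <- dim(X)[3]
    H <- array(0, c(2L * h, B, n))
    H[seq_len(h), , ] <- f$H
    H[h + seq_len(h), , ] <- b$H
    cache$f <- f; cache$b <- b; cache$H <- H
  }
  if (cfg$variant == "rnn") {
    h <- cfg$lstm_units
    B <- dim(X)[2]
    rep <- matrix(0, 2L * h, B)
    for (bb in seq_len(B)) {
      rep[seq_len(h), bb] <- cache$f$H[seq_len(h), bb, side$nvalid[bb]]
      rep[h + seq_len(h), bb] <- cache$b$H[seq_len(h), bb, 1L]
    }
    cache$rep <- rep
  } else {
    Hin <- if (cfg$variant == "cnn") X else cache$H
    cv <- .conv_forward_cpp(Hin, as.integer(side$nvalid), params$conv$W,
                            params$conv$b, cfg$conv_widths)
    cache$conv <- cv
    cache$rep <- cv$C
  }
  cache
}

backward_side <- function(params, cfg, cache, drep) {
  side <- cache$side
  d <- cfg$word_dim + cfg$pos_dim
  B <- dim(cache$X)[2]; n <- dim(cache$X)[3]
  grads <- list()
  if (cfg$variant == "rnn") {
    h <- cfg$lstm_units
    dH <- array(0, c(2L * h, B, n))
    for (bb in seq_len(B)) {
      dH[seq_len(h), bb, side$nvalid[bb]] <- drep[seq_len(h), bb]
      dH[h + seq_len(h), bb, 1L] <- drep[h + seq_len(h), bb]
    }
  } else {
    Hin <- if (cfg$variant == "cnn") cache$X else cache$H
    cb <- .conv_backward_cpp(drep, Hin, cache$conv$C, cache$conv$argmax,
                             params$conv$W, cfg$conv_widths)
    wn <- names(params$conv$W)
    grads$conv <- list(W = stats::setNames(as.list(cb$dW), wn),
                       b = stats::setNames(as.list(cb$db), wn))
    dH <- cb$dH
  }
  if (cfg$variant == "cnn") {
    dX <- dH
  } else {
    h <- cfg$lstm_units
    dHf <- dH[seq_len(h), , , drop = FALSE]
    dHb <- dH[h + seq_len(h), , , drop = FALSE]
    dim(dHf) <- c(h, B, n); dim(dHb) <- c(h, B, n)
    gf <- .lstm_backward_cpp(dHf, cache$X, side$mask, cache$f$H, cache$f$C,
                             cache$f$I, cache$f$F, cache$f$G, cache$f$O,
                             params$lstm_f$Wx, params$lstm_f$Wh,
                             params$lstm_f$Pi, params$lstm_f$Pf,
                             params$lstm_f$Po, params$lstm_f$b, FALSE)
    gb <- .lstm_backward_cpp(dHb, cache$X, side$mask, cache$b$H, cache$b$C,
                             cache$b$I, cache$b$F, cache$b$G, cache$b$O,
                             params$lstm_b$Wx, params$lstm_b$Wh,
                             params$lstm_b$Pi, params$lstm_b$Pf,
                             params$lstm_b$Po, params$lstm_b$b, TRUE)
    grads$lstm_f <- list(Wx = gf$dWx, Wh = gf$dWh, Pi = gf$dPi, Pf = gf$dPf,
                         Po = gf$dPo, b = as.numeric(gf$db))
    grads$lstm_b <- list(Wx = gb$dWx, Wh = gb$dWh, Pi = gb$dPi, Pf = gb$dPf,
                         Po = gb$dPo, b = as.numeric(gb$db))
    dX <- gf$dX + gb$dX
  }
  # scatter into embedding gradients
  dXw <- matrix(dX[seq_len(cfg$word_dim), , ], nrow = cfg$word_dim)
  dXp <- matrix(dX[cfg$word_dim + seq_len(cfg$pos_dim), , ], nrow = cfg$pos_dim)
  grads$Ew <- scatter_columns(dXw, as.vector(side$tok), ncol(params$Ew))
  grads$Ed <- scatter_columns(dXp, as.vector(side$pos), ncol(params$Ed))
  grads
}

# accumulate columns of `m` into a zero matrix by column id
scatter_columns <- function(m, ids, ncols) {
  agg <- rowsum(t(m), group = ids)       # (n_unique x d), rownames = ids
  out <- matrix(0, nrow(m), ncols)
  out[, as.integer(rownames(agg))] <- t(agg)
  out
}

softmax_cols <- function(a) {
  a <- sweep(a, 2, apply(a, 2, max))
  e <- exp(a)
  sweep(e, 2, colSums(e), "/")
}

# full-network forward (and optional backward) for one batch.
# batch: list(me = side, te = side, zrows = 10 x B matrix of E_g columns,
#             y = integer labels in 1..4 or NULL)
nn_batch <- function(params, cfg, batch, train = FALSE, compute_grads = FALSE) {
  me_cache <- forward_side(params, cfg, batch$me)
  te_cache <- forward_side(params, cfg, batch$te)
  B <- ncol(me_cache$rep)
  Z <- matrix(params$Eg[, as.vector(batch$zrows)], nrow = 10L * cfg$feat_dim)
  feat <- rbind(me_cache$rep, te_cache$rep, Z)
  dropmask <- NULL
  if (train && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    dropmask <- matrix(rbinom(length(feat), 1, keep), nrow(feat)) / keep
    feat <- feat * dropmask
  }
  A <- params$Wo %*% feat + params$bo
  probs <- softmax_cols(A)
  out <- list(probs = probs)
  if (!is.null(batch$y)) {
    p_true <- probs[cbind(batch$y, seq_len(B))]
    out$loss <- -mean(log(pmax(p_true, 1e-12)))
  }
  if (compute_grads) {
    stopifnot(!is.null(batch$y))
    Yhot <- matrix(0, 4L, B)
    Yhot[cbind(batch$y, seq_len(B))] <- 1
    dA <- (probs - Yhot) / B
    grads <- list(
      Wo = dA %*% t(feat),
      bo = rowSums(dA)
    )
    dfeat <- t(params$Wo) %*% dA
    if (!is.null(dropmask)) dfeat <- dfeat * dropmask
    rd <- rep_dim(cfg)
    dme <- dfeat[seq_len(rd), , drop = FALSE]
    dte <- dfeat[rd + seq_len(rd), , drop = FALSE]
    dZ <- dfeat[2L * rd + seq_len(10L * cfg$feat_dim), , drop = FALSE]
    g_me <- backward_side(params, cfg, me_cache, dme)
    g_te <- backward_side(params, cfg, te_cache, dte)
    grads <- merge_grads(grads, g_me)
    grads <- merge_grads(grads, g_te)
    dZmat <- matrix(dZ, nrow = cfg$feat_dim)
    grads$Eg <- scatter_columns(dZmat, as.vector(batch$zrows), ncol(params$Eg))
    out$grads <- grads
  }
  out
}

merge_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) {
      a[[nm]] <- b[[nm]]
    } else if (is.list(b[[nm]])) {
      a[[nm]] <- merge_grads(a[[nm]], b[[nm]])
    } else {
      a[[nm]] <- a[[nm]] + b[[nm]]
    }
  }
  a
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) {
      params[[nm]] <- sgd_step(params[[nm]], grads[[nm]], lr)
    } else {
      params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    }
  }
  params
}
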