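# Hand-built fixture notes with exactly known spans, plus independent
# oracles (naive sliding-window convolution, step-by-step LSTM gate
# arithmetic, numeric gradients) used across the test files.

# A two-section note, spans laid out by concatenation so offsets are exact.
#   section 1 "History of present illness":
#     sentence 1: "于2011-10-09出现发热。"   (TE t1, entity m1)
#     sentence 2: "于2011-10-13行手术。"     (TE t2)
#   section 2 "Physical examination":
#     sentence 3: "查体见水肿。"             (entity m2)
# plus an intro "Other" section holding the admission TE t0.
fixture_note <- function(gold_m1 = NA, gold_m2 = NA) {
  parts <- c(
    intro1 = "患者于", adm = "2011-10-01", intro2 = "入院。\n",
    hdr1 = "现病史：",
    s1a = "于", t1 = "2011-10-09", s1b = "出现", m1 = "发热", s1c = "。",
    s2a = "于", t2 = "2011-10-13", s2b = "行手术。\n",
    hdr2 = "体格检查：",
    s3a = "查体见", m2 = "水肿", s3b = "。"
  )
  ends <- cumsum(nchar(parts))
  starts <- ends - nchar(parts)
  sp <- function(nm) c(starts[[nm]], ends[[nm]])
  text <- paste(parts, collapse = "")
  clinical_note(
    "fx1", text,
    sections = tibble::tibble(
      name = c("Other", "History of present illness", "Physical examination"),
      start = c(0L, starts[["hdr1"]], starts[["hdr2"]]),
      end = c(starts[["hdr1"]], starts[["hdr2"]], nchar(text))
    ),
    entities = tibble::tibble(
      me_id = c("m1", "m2"),
      start = c(sp("m1")[1], sp("m2")[1]),
      end = c(sp("m1")[2], sp("m2")[2]),
      gold_index = c(gold_m1, gold_m2)
    ),
    temporal_expressions = tibble::tibble(
      te_id = c("t0", "t1", "t2"),
      start = c(sp("adm")[1], sp("t1")[1], sp("t2")[1]),
      end = c(sp("adm")[2], sp("t1")[2], sp("t2")[2]),
      value = c("2011-10-01", "2011-10-09", "2011-10-13"),
      kind = c("admission", "other", "other")
    ),
    admission_te = "t0"
  )
}

# note with n TEs at the given ISO values, no entities
timeline_note <- function(values) {
  if (length(values) == 0) {
    return(clinical_note("tl0", "无时间。",
      sections = tibble::tibble(name = "Other", start = 0L, end = 4L),
      entities = tibble::tibble(me_id = character(), start = integer(),
                                end = integer()),
      temporal_expressions = tibble::tibble(
        te_id = character(), start = integer(), end = integer(),
        value = character(), kind = character())))
  }
  text <- paste0(paste(values, collapse = " "), "。")
  starts <- cumsum(c(0, nchar(values[-length(values)]) + 1))
  clinical_note("tl1", text,
    sections = tibble::tibble(name = "Other", start = 0L, end = nchar(text)),
    entities = tibble::tibble(me_id = character(), start = integer(),
                              end = integer()),
    temporal_expressions = tibble::tibble(
      te_id = paste0("t", seq_along(values)),
      start = as.integer(starts),
      end = as.integer(starts + nchar(values)),
      value = values,
      kind = "other"))
}

# independent timeline oracle: merge equal values, number nodes/intervals
brute_force_timeline_ids <- function(values) {
  n_nodes <- length(unique(values))
  0:(2L * n_nodes)
}

# independent single-step LSTM gate arithmetic (scalar or vector states)
oracle_lstm_step <- function(x, h_prev, c_prev, p) {
  h <- length(h_prev)
  a <- p$Wx %*% x + p$Wh %*% h_prev + p$b
  i <- plogis(a[seq_len(h)] + p$Pi %*% c_prev)
  f <- plogis(a[h + seq_len(h)] + p$Pf %*% c_prev)
  g <- tanh(a[2 * h + seq_len(h)])
  c_t <- f * c_prev + i * g
  o <- plogis(a[3 * h + seq_len(h)] + p$Po %*% c_t)
  list(h = as.numeric(o * tanh(c_t)), c = as.numeric(c_t))
}

oracle_lstm_run <- function(X, p, reverse = FALSE) {
  n <- nrow(X)
  h <- ncol(p$Wh)
  H <- matrix(0, n, h)
  hs <- numeric(h); cs <- numeric(h)
  for (t in (if (reverse) n:1 else 1:n)) {
    st <- oracle_lstm_step(X[t, ], hs, cs, p)
    hs <- st$h; cs <- st$c
    H[t, ] <- hs
  }
  H
}

# brute-force convolution + max-pool oracle: explicit loops over windows
oracle_conv_maxpool <- function(H, bank, n_real = nrow(H)) {
  out <- c()
  for (w in seq_along(bank$widths)) {
    k <- bank$widths[w]
    W <- bank$W[[w]]; b <- bank$b[[w]]
    nwin <- min(nrow(H) - k + 1, n_real)
    for (f in seq_len(nrow(W))) {
      vals <- sapply(seq_len(nwin), function(j) {
        win <- as.numeric(t(H[j:(j + k - 1), , drop = FALSE]))
        plogis(sum(W[f, ] * win) + b[f])
      })
      out <- c(out, max(vals))
    }
  }
  out
}

# small random parameter set for layer tests
random_lstm_params <- function(d, h, scale = 0.5) {
  r <- function(nr, nc) matrix(runif(nr * nc, -scale, scale), nr, nc)
  list(Wx = r(4 * h, d), Wh = r(4 * h, h), Pi = r(h, h), Pf = r(h, h),
       Po = r(h, h), b = runif(4 * h, -scale, scale))
}

random_conv_bank <- function(D, widths = c(2, 3), nf = 2, scale = 0.5) {
  r <- function(nr, nc) matrix(runif(nr * nc, -scale, scale), nr, nc)
  list(W = lapply(widths, function(k) r(nf, k * D)),
       b = lapply(seq_along(widths), function(i) runif(nf, -scale, scale)),
       widths = widths)
}

# central-difference gradient of the batch loss wrt one parameter
numeric_grad <- function(params, path, loss_fn, eps = 1e-5) {
  get_p <- function(p) { for (k in path) p <- p[[k]]; p }
  set_p <- function(p, path, v) {
    if (length(path) == 1) { p[[path]] <- v; return(p) }
    p[[path[1]]] <- set_p(p[[path[1]]], path[-1], v)
    p
  }
  w <- get_p(params)
  g <- array(0, dim = if (is.null(dim(w))) length(w) else dim(w))
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- w[i] + eps
    wm <- w; wm[i] <- w[i] - eps
    g[i] <- (loss_fn(set_p(params, path, wp)) -
               loss_fn(set_p(params, path, wm))) / (2 * eps)
  }
  g
}

# tiny-dimension configuration for fast unit tests
tiny_config <- function(...) {
  defaults <- list(word_dim = 8L, pos_dim = 4L, feat_dim = 3L,
                   lstm_units = 5L, conv_widths = c(2L, 3L),
                   conv_filters = 4L, max_len = 30L, dropout = 0,
                   batch_size = 8L, epochs = 2L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# shared small corpora (built once per test run)
shared_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_corpus(12, seed = 11)
    cache
  }
})
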