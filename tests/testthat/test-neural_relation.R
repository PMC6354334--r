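# A tiny trained-at-init model whose embedding tables the input-layer tests
# can interrogate directly.
tiny_model <- function(cfg = tiny_config(), seed = 99) {
  set.seed(seed)
  vocab <- c("[PAD]", "[UNK]", "于", "出", "现", "发热", "2011", "年", "。")
  tables <- rep(list(c("a", "b", "OTHER")), 10)
  names(tables) <- paste0("f", 1:10)
  params <- medtimeline:::init_relation_params(cfg, vocab, tables)
  structure(list(config = cfg, vocab = vocab, feature_tables = tables,
                 params = params, classes = relation_classes()),
            class = "mt_relation_model")
}

test_that("encode_input concatenates word and position lookups", {
  m <- tiny_model()
  toks <- c("于", "2011", "年", "出", "现", "发热", "。")
  enc <- encode_input(toks, target = 6, m)
  expect_equal(enc$positions, (1:7) - 6)
  expect_equal(enc$positions[enc$k], 0)
  d <- m$config$word_dim + m$config$pos_dim
  expect_equal(ncol(enc$X), d)
  # elementwise against direct table lookups
  for (t in seq_along(toks)) {
    wid <- match(toks[t], m$vocab)
    pid <- (t - 6) + m$config$max_len
    expect_equal(as.numeric(enc$X[t, ]),
                 c(m$params$Ew[, wid], m$params$Ed[, pid]))
  }
  # unknown token maps to [UNK]
  enc2 <- encode_input(c("somethingnew", "于"), 2, m)
  expect_equal(as.numeric(enc2$X[1, seq_len(m$config$word_dim)]),
               as.numeric(m$params$Ew[, 2]))
  expect_error(encode_input(character(), 1, m), class = "medtimeline_nn_error")
})

test_that("the input row width is word dim + position dim (80 by default)", {
  cfg <- model_config()
  expect_equal(cfg$word_dim + cfg$pos_dim, 80L)
  expect_equal(cfg$word_dim, 50L)
  expect_equal(cfg$pos_dim, 30L)
})

test_that("embed_features selects embedding columns and concatenates them", {
  m <- tiny_model()
  Eg <- m$params$Eg
  one_hots <- rep(list(c(0, 1, 0)), 10)
  Z <- embed_features(one_hots, Eg)
  expect_length(Z, 10 * m$config$feat_dim)
  for (i in 1:10) {
    expect_equal(Z[(i - 1) * 3 + 1:3], as.numeric(Eg[, (i - 1) * 3 + 2]))
  }
  # default dimensions give the published fused width 10 x 20 = 200
  expect_equal(10L * model_config()$feat_dim, 200L)
  expect_error(embed_features(rep(list(c(1, 0)), 10), Eg),
               class = "medtimeline_nn_error")
})

test_that("an all-zero LSTM produces all-zero states", {
  d <- 4; h <- 3; n <- 5
  p <- list(Wx = matrix(0, 4 * h, d), Wh = matrix(0, 4 * h, h),
            Pi = matrix(0, h, h), Pf = matrix(0, h, h), Po = matrix(0, h, h),
            b = numeric(4 * h))
  X <- matrix(rnorm(n * d), n, d)
  H <- lstm_sequence(X, p, p)
  expect_equal(H, matrix(0, n, 2 * h))
})

test_that("a scalar peephole cell matches hand-evaluated gate arithmetic", {
  # 1-unit cell, 1-dim input, hand-set weights; two steps evaluated with the
  # independent step oracle
  p <- list(Wx = matrix(c(0.5, -0.3, 0.8, 0.2), 4, 1),
            Wh = matrix(c(0.1, 0.4, -0.2, 0.3), 4, 1),
            Pi = matrix(0.25, 1, 1), Pf = matrix(-0.5, 1, 1),
            Po = matrix(0.75, 1, 1), b = c(0.05, -0.05, 0.1, 0))
  X <- matrix(c(1, -2), 2, 1)
  H <- lstm_sequence(X, p)
  s1 <- oracle_lstm_step(1, 0, 0, p)
  s2 <- oracle_lstm_step(-2, s1$h, s1$c, p)
  expect_equal(H[1, 1], s1$h, tolerance = 1e-6)
  expect_equal(H[2, 1], s2$h, tolerance = 1e-6)
})

test_that("the backward direction equals the forward direction on reversed input", {
  set.seed(14)
  d <- 6; h <- 4; n <- 7
  p <- random_lstm_params(d, h)
  X <- matrix(rnorm(n * d), n, d)
  Hfwd_on_rev <- lstm_sequence(X[n:1, ], p)
  Hbi <- lstm_sequence(X, p, p)
  Hb <- Hbi[, h + seq_len(h)]
  expect_equal(Hb, Hfwd_on_rev[n:1, ], tolerance = 1e-10)
})

test_that("multi-step LSTM output matches the step-by-step oracle", {
  set.seed(15)
  d <- 5; h <- 3; n <- 6
  p <- random_lstm_params(d, h)
  X <- matrix(rnorm(n * d), n, d)
  expect_equal(lstm_sequence(X, p), oracle_lstm_run(X, p), tolerance = 1e-8)
})

test_that("convolution yields n - k + 1 windows and sigmoid(0) under zero weights", {
  D <- 4; n <- 10
  bank <- list(W = list(matrix(0, 2, 3 * D)), b = list(c(0, 0)), widths = 3L)
  H <- matrix(rnorm(n * D), n, D)
  C <- conv_maxpool(H, bank)
  expect_equal(C, c(0.5, 0.5))
  # window count observed through a filter that picks out one coordinate
  W1 <- matrix(0, 1, 3 * D); W1[1, 1] <- 1
  bank2 <- list(W = list(W1), b = list(0), widths = 3L)
  # the max over sigmoid(H[j,1]) for j = 1..n-k+1: position n-1 and n never
  # start a window
  expect_equal(conv_maxpool(H, bank2),
               max(plogis(H[seq_len(n - 2), 1])))
})

test_that("conv_maxpool matches the brute-force sliding-window oracle", {
  set.seed(16)
  D <- 5; n <- 6
  bank <- random_conv_bank(D, widths = c(2L, 3L), nf = 2)
  H <- matrix(rnorm(n * D), n, D)
  expect_equal(conv_maxpool(H, bank), oracle_conv_maxpool(H, bank),
               tolerance = 1e-6)
  # padded rows are excluded once n_real marks them
  H2 <- rbind(H, matrix(9, 2, D))
  expect_equal(conv_maxpool(H2, bank, n_real = n),
               oracle_conv_maxpool(H2, bank, n_real = n), tolerance = 1e-6)
})

test_that("classify_pair returns a proper 4-class distribution", {
  m <- tiny_model()
  me <- list(tokens = c("出", "现", "发热", "。"), k = 3L)
  te <- list(tokens = c("于", "2011", "年", "。"), k = 2L)
  fv <- structure(setNames(rep("a", 10), paste0("f", 1:10)),
                  class = "mt_feature_vector")
  y <- classify_pair(m, me, te, fv)
  expect_named(y, c("NONE", "SIMULTANEOUS", "BEFORE", "AFTER"))
  expect_equal(sum(y), 1, tolerance = 1e-9)
  expect_true(all(y > 0 & y < 1))
})

test_that("classify_pair equals the composition of the exported layer oracles", {
  m <- tiny_model()
  cfg <- m$config
  me <- list(tokens = c("出", "现", "发热", "。"), k = 3L)
  te <- list(tokens = c("于", "2011", "年", "。"), k = 2L)
  fv <- structure(setNames(rep("b", 10), paste0("f", 1:10)),
                  class = "mt_feature_vector")
  y <- classify_pair(m, me, te, fv)

  rep_of <- function(e) {
    enc <- encode_input(e$tokens, e$k, m)
    n <- nrow(enc$X)
    # pad to the largest filter width as the batched path does
    n_pad <- max(n, max(cfg$conv_widths))
    pad_row <- c(m$params$Ew[, 1], m$params$Ed[, 2 * cfg$max_len])
    X <- enc$X
    if (n_pad > n) {
      X <- rbind(X, matrix(pad_row, n_pad - n, ncol(X), byrow = TRUE))
    }
    H <- lstm_sequence(X, m$params$lstm_f, m$params$lstm_b,
                       mask = c(rep(1, n), rep(0, n_pad - n)))
    bank <- list(W = m$params$conv$W, b = m$params$conv$b,
                 widths = cfg$conv_widths)
    conv_maxpool(H, bank, n_real = n)
  }
  oh <- encode_one_hot(fv, m$feature_tables)
  Z <- embed_features(oh, m$params$Eg)
  feat <- c(rep_of(me), rep_of(te), Z)
  a <- as.numeric(m$params$Wo %*% feat + m$params$bo)
  expected <- exp(a - max(a)) / sum(exp(a - max(a)))
  expect_equal(unname(y), expected, tolerance = 1e-6)
})

test_that("appending PAD steps never changes the prediction", {
  m <- tiny_model()
  cfg <- m$config
  enc <- list(tokens = c("于", "2011", "出", "现", "发热"), positions = c(-4:0),
              k = 5L)
  fv_rows <- matrix(medtimeline:::feature_row_indices(
    structure(setNames(rep("a", 10), paste0("f", 1:10)),
              class = "mt_feature_vector"), m$feature_tables), ncol = 1)
  run_with_pad <- function(extra) {
    side <- medtimeline:::batch_side(list(enc), 1L, m$vocab, cfg)
    if (extra > 0) {
      n <- side$n
      side$tok <- cbind(side$tok, matrix(1L, 1, extra))
      side$pos <- cbind(side$pos, matrix(2L * cfg$max_len, 1, extra))
      side$mask <- cbind(side$mask, matrix(0, 1, extra))
      side$n <- n + extra
    }
    batch <- list(me = side, te = side, zrows = fv_rows, y = NULL)
    medtimeline:::nn_batch(m$params, cfg, batch, train = FALSE)$probs[, 1]
  }
  base <- run_with_pad(0)
  expect_equal(run_with_pad(3), base, tolerance = 1e-6)
  expect_equal(run_with_pad(10), base, tolerance = 1e-6)
})

test_that("the default configuration carries the published hyper-parameters", {
  cfg <- model_config()
  expect_equal(cfg$word_dim, 50L)
  expect_equal(cfg$pos_dim, 30L)
  expect_equal(cfg$feat_dim, 20L)
  expect_equal(cfg$lstm_units, 50L)
  expect_equal(cfg$conv_widths, c(3L, 5L, 7L))
  expect_equal(cfg$conv_filters, 100L)
  expect_equal(cfg$max_len, 100L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 20L)
})

test_that("one small SGD step decreases the loss on a fixed batch", {
  set.seed(23)
  co <- generate_corpus(3, seed = 23)
  cfg <- tiny_config()
  pairs <- candidate_pairs(co)[1:8, ]
  enc <- medtimeline:::pair_sentence_encodings(pairs, co, cfg$max_len)
  vocab <- medtimeline:::build_vocab(enc)
  tables <- build_feature_tables(enc$features)
  params <- medtimeline:::init_relation_params(cfg, vocab, tables)
  zrows <- vapply(enc$features, medtimeline:::feature_row_indices,
                  numeric(10), category_tables = tables)
  batch <- list(me = medtimeline:::batch_side(enc$me, 1:8, vocab, cfg),
                te = medtimeline:::batch_side(enc$te, 1:8, vocab, cfg),
                zrows = zrows[, 1:8],
                y = match(pairs$gold_relation, relation_classes()))
  out <- medtimeline:::nn_batch(params, cfg, batch, train = FALSE,
                                compute_grads = TRUE)
  params2 <- medtimeline:::sgd_step(params, out$grads, 0.05)
  out2 <- medtimeline:::nn_batch(params2, cfg, batch, train = FALSE)
  expect_lt(out2$loss, out$loss)
})

test_that("a small model fits trivially separable pairs almost perfectly", {
  # anchor-only corpus: each entity keeps a single candidate pair whose label
  # is fully determined by its section, so the pairs are linearly separable
  # through the feature representation alone
  co <- generate_corpus(20, seed = 29)
  man <- attr(co, "manifest")
  co <- structure(lapply(co, function(note) {
    keep <- man$me_id[man$note_id == note$note_id &
                        man$mechanism == "anchor"]
    note$entities <- note$entities[note$entities$me_id %in% keep, ]
    note
  }), class = "mt_corpus")
  pairs <- candidate_pairs(co)
  expect_gte(nrow(pairs), 150)
  expect_true(all(pairs$gold_relation != "NONE"))
  cfg <- tiny_config(epochs = 20L, dropout = 0.2, batch_size = 16L)
  m <- train_relation_model(co, cfg, seed = 4)
  pp <- medtimeline:::predicted_relations(predict(m, co))
  acc <- mean(pp$pred_relation == pp$gold_relation)
  expect_gte(acc, 0.99)
  expect_lt(tail(m$loss_log$loss, 1), 0.5 * m$loss_log$loss[1])
})

test_that("training labels outside the class set are rejected", {
  co <- generate_corpus(2, seed = 30)
  co[[1]]$entities$gold_index[1] <- NA_integer_
  expect_error(train_relation_model(co, tiny_config()), "gold")
})

test_that("training is bit-reproducible under a fixed seed", {
  co <- generate_corpus(3, seed = 31)
  cfg <- tiny_config(epochs = 2L, dropout = 0.5)
  m1 <- train_relation_model(co, cfg, seed = 8)
  m2 <- train_relation_model(co, cfg, seed = 8)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_log, m2$loss_log)
  m3 <- train_relation_model(co, cfg, seed = 9)
  expect_false(identical(m3$params$Wo, m1$params$Wo))
})

test_that("model save/load restores bit-identical predictions", {
  co <- generate_corpus(3, seed = 33)
  cfg <- tiny_config(epochs = 1L)
  m <- train_relation_model(co, cfg, seed = 2)
  dir <- withr::local_tempdir()
  save_relation_model(m, dir)
  m2 <- load_relation_model(dir)
  p1 <- predict(m, co)
  p2 <- predict(m2, co)
  expect_identical(p1, p2)
})

test_that("word2vec text files import and initialize the embedding table", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("3 4",
               "发热 0.1 0.2 0.3 0.4",
               "头痛 -1 0 1 2",
               "于 0.5 0.5 0.5 0.5"), f)
  emb <- read_word2vec(f)
  expect_equal(emb$vocab, c("发热", "头痛", "于"))
  expect_equal(dim(emb$vectors), c(4L, 3L))
  expect_equal(emb$vectors[, 2], c(-1, 0, 1, 2))
  cfg <- tiny_config(word_dim = 4L)
  set.seed(1)
  params <- medtimeline:::init_relation_params(
    cfg, c("[PAD]", "[UNK]", "发热", "新词"),
    rep(list(c("a", "OTHER")), 10), embeddings = emb)
  expect_equal(params$Ew[, 3], c(0.1, 0.2, 0.3, 0.4))
  # out-of-table word keeps its random initialization within [-1, 1]
  expect_true(all(abs(params$Ew[, 4]) <= 1))
  writeLines(c("junk header", "a 1 2"), f)
  expect_error(read_word2vec(f), class = "medtimeline_parse_error")
})
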