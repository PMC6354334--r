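#' Rule-based temporal indexing
#'
#' Deterministic baseline driven by the section/anchor table. For each entity
#' the ordered rules are tried and the first match fires:
#' \describe{
#'   \item{`sentence_front`}{a temporal expression precedes the entity in its
#'     sentence: pick the nearest preceding one, relation SIMULTANEOUS;}
#'   \item{`sentence_behind`}{an expression follows the entity in the same
#'     sentence: nearest following one, SIMULTANEOUS;}
#'   \item{`section_front`}{an expression precedes the entity in its section:
#'     nearest preceding one, SIMULTANEOUS;}
#'   \item{`section_anchor`}{fall back to the section's anchor time with the
#'     section's anchor relation.}
#' }
#' Every decision records the rule that fired, so deviations are auditable.
#'
#' @param corpus An `mt_corpus`.
#' @param rule_order Character vector naming the rules in firing order (a
#'   YAML list read with `yaml::read_yaml()` plugs in directly).
#' @return Tibble with one row per entity: `note_id`, `me_id`, `te_id`,
#'   `relation`, `rule`, `confidence` (always 1) and `pred_index`.
#' @export
rule_based_index <- function(corpus,
                             rule_order = c("sentence_front", "sentence_behind",
                                            "section_front", "section_anchor")) {
  purrr::map_dfr(corpus, function(note) {
    if (nrow(note$entities) == 0) return(NULL)
    tl <- build_timeline(note)
    sentences <- segment_sentences(note)
    tes <- note$temporal_expressions
    te_sent <- vapply(seq_len(nrow(tes)), function(i) {
      sentence_of_span(sentences, tes$start[i], tes$end[i])
    }, integer(1))
    purrr::map_dfr(note$entities$me_id, function(me_id) {
      me <- note$entities[note$entities$me_id == me_id, ]
      sec_i <- section_of_span(note, me$start, me$end)
      sec <- note$sections[sec_i, ]
      me_sent <- sentence_of_span(sentences, me$start, me$end)
      in_sec <- tes$start >= sec$start & tes$end <= sec$end
      decision <- NULL
      for (rule in rule_order) {
        hit <- switch(rule,
          sentence_front = {
            i <- which(te_sent == me_sent & tes$start < me$start)
            if (length(i)) i[which.max(tes$start[i])]
          },
          sentence_behind = {
            i <- which(te_sent == me_sent & tes$start >= me$start)
            if (length(i)) i[which.min(tes$start[i])]
          },
          section_front = {
            i <- which(in_sec & tes$start < me$start)
            if (length(i)) i[which.max(tes$start[i])]
          },
          section_anchor = -1L,
          abort(sprintf("unknown rule '%s'", rule))
        )
        if (is.null(hit) || length(hit) == 0) next
        if (identical(hit, -1L)) {
          te_id <- section_anchor_te(sec, note)
          relation <- c(Before = "BEFORE", Simultaneous = "SIMULTANEOUS",
                        After = "AFTER")[[sec$anchor_relation]]
        } else {
          te_id <- tes$te_id[hit]
          relation <- "SIMULTANEOUS"
        }
        decision <- tibble(
          note_id = note$note_id, me_id = me_id, te_id = te_id,
          relation = relation, rule = rule, confidence = 1,
          pred_index = relation_to_index(te_id, relation, tl)
        )
        break
      }
      if (is.null(decision)) {
        abort(sprintf("note '%s': no rule fired for entity '%s'",
                      note$note_id, me_id))
      }
      decision
    })
  })
}

# ---------------------------------------------------------------------------
# linear SVM baseline

svm_bag_tokens <- function(enc, window) {
  k <- enc$k
  lo <- max(1L, k - window)
  hi <- min(length(enc$tokens), k + window)
  enc$tokens[setdiff(lo:hi, k)]
}

svm_instance_matrix <- function(encodings, zonehots, vocab, n_feat_cols) {
  N <- length(encodings$me)
  V <- length(vocab)
  X <- matrix(0, N, 2L * V + n_feat_cols)
  for (i in seq_len(N)) {
    mb <- match(svm_bag_tokens(encodings$me[[i]], attr(vocab, "window")), vocab)
    tb <- match(svm_bag_tokens(encodings$te[[i]], attr(vocab, "window")), vocab)
    mb[is.na(mb)] <- V  # OTHER
    tb[is.na(tb)] <- V
    X[i, unique(mb)] <- 1
    X[i, V + unique(tb)] <- 1
  }
  X[, 2L * V + seq_len(n_feat_cols)] <- zonehots
  X
}

#' Train the linear SVM relation baseline
#'
#' Sparse indicator input: bag of context words in a +/- `window`-token
#' window around the entity target, the same for the expression target, and
#' the one-hot relation features. Four one-vs-rest linear machines
#' (`e1071::svm`) are fitted; class probabilities are the softmax of the four
#' decision values, so the ensemble can average them directly.
#'
#' @param corpus Training `mt_corpus` with gold indices.
#' @param window Context half-window in tokens (default 5).
#' @param cost SVM cost parameter (default 1).
#' @param max_len Sentence length cap, as in [model_config()].
#' @return An `mt_svm_model`.
#' @export
train_svm_model <- function(corpus, window = 5L, cost = 1, max_len = 100L) {
  pairs <- candidate_pairs(corpus)
  if (any(is.na(pairs$gold_relation))) {
    abort("training corpus has entities without gold indices")
  }
  enc <- pair_sentence_encodings(pairs, corpus, max_len)
  toks <- unique(unlist(c(lapply(enc$me, svm_bag_tokens, window = window),
                          lapply(enc$te, svm_bag_tokens, window = window))))
  vocab <- c(sort(toks), "[OTHER]")
  attr(vocab, "window") <- as.integer(window)
  feature_tables <- build_feature_tables(enc$features)
  onehots <- t(vapply(enc$features, function(fv) {
    unlist(encode_one_hot(fv, feature_tables))
  }, numeric(sum(vapply(feature_tables, length, integer(1))))))
  X <- svm_instance_matrix(enc, onehots, vocab, ncol(onehots))
  y <- pairs$gold_relation
  if (length(unique(y)) < 2) {
    abort("SVM training needs at least two relation classes")
  }
  machines <- lapply(relation_classes(), function(cls) {
    lab <- factor(ifelse(y == cls, "pos", "rest"), levels = c("pos", "rest"))
    if (length(unique(lab)) < 2) return(NULL)   # class absent in training
    e1071::svm(X, lab, kernel = "linear", cost = cost, scale = FALSE,
               fitted = FALSE)
  })
  structure(list(
    machines = stats::setNames(machines, relation_classes()),
    vocab = vocab, feature_tables = feature_tables,
    window = as.integer(window), max_len = as.integer(max_len),
    classes = relation_classes()
  ), class = "mt_svm_model")
}

#' @export
print.mt_svm_model <- function(x, ...) {
  cat(sprintf("<mt_svm_model> one-vs-rest linear SVM, vocab %d, window +/-%d\n",
              length(x$vocab), x$window))
  invisible(x)
}

#' @export
glance.mt_svm_model <- function(x, ...) {
  tibble(model = "svm", vocab_size = length(x$vocab), window = x$window)
}

#' Predict relation probabilities with the SVM baseline
#'
#' @param object An `mt_svm_model`.
#' @param corpus An `mt_corpus`.
#' @param pairs Optional pre-computed [candidate_pairs()].
#' @param ... Unused.
#' @return Pairs tibble with `p_none`, `p_simultaneous`, `p_before`,
#'   `p_after` columns (softmax over one-vs-rest decision values).
#' @export
predict.mt_svm_model <- function(object, corpus, pairs = NULL, ...) {
  if (is.null(pairs)) pairs <- candidate_pairs(corpus)
  enc <- pair_sentence_encodings(pairs, corpus, object$max_len)
  onehots <- t(vapply(enc$features, function(fv) {
    unlist(encode_one_hot(fv, object$feature_tables))
  }, numeric(sum(vapply(object$feature_tables, length, integer(1))))))
  X <- svm_instance_matrix(enc, onehots, object$vocab, ncol(onehots))
  dec <- sapply(object$classes, function(cls) {
    m <- object$machines[[cls]]
    if (is.null(m)) return(rep(-1e6, nrow(X)))
    d <- attr(predict(m, X, decision.values = TRUE), "decision.values")
    v <- as.numeric(d[, 1])
    # decision-value sign follows the class named first in the column label
    if (startsWith(colnames(d)[1], "rest/")) v <- -v
    v
  })
  dec <- matrix(dec, nrow = nrow(X))
  probs <- t(softmax_cols(t(dec)))
  pairs$p_none <- probs[, 1]
  pairs$p_simultaneous <- probs[, 2]
  pairs$p_before <- probs[, 3]
  pairs$p_after <- probs[, 4]
  pairs
}
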