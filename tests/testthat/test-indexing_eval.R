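# helper: prediction tibble for the fixture note's pair universe
fx_pred_pairs <- function(note, probs) {
  pairs <- candidate_pairs(list(note))
  stopifnot(nrow(probs) == nrow(pairs))
  pairs[, c("p_none", "p_simultaneous", "p_before", "p_after")] <- probs
  pairs
}

test_that("select_index picks the highest non-NONE probability", {
  note <- fixture_note(gold_m1 = 3L, gold_m2 = 1L)
  # pairs: m1 x (t0, t1, t2), m2 x t0
  probs <- rbind(
    c(0.9, 0.02, 0.04, 0.04),   # m1-t0: confident NONE, never selectable
    c(0.1, 0.5, 0.2, 0.2),      # m1-t1: S = 0.5
    c(0.1, 0.1, 0.6, 0.2),      # m1-t2: B = 0.6 -> wins
    c(0.1, 0.7, 0.1, 0.1)       # m2-t0
  )
  sel <- select_index(fx_pred_pairs(note, probs), list(note))
  m1 <- sel[sel$me_id == "m1", ]
  expect_equal(m1$te_id, "t2")
  expect_equal(m1$relation, "BEFORE")
  expect_equal(m1$pred_index, te_node_id(build_timeline(note), "t2") - 1L)
  expect_equal(m1$confidence, 0.6)
  m2 <- sel[sel$me_id == "m2", ]
  expect_equal(m2$pred_index, 1L)
  expect_equal(m2$relation, "SIMULTANEOUS")
})

test_that("ties break by character distance, then candidate order", {
  note <- fixture_note(gold_m1 = 3L, gold_m2 = 1L)
  # equal top probability (SIMULTANEOUS) on every candidate of m1: the
  # nearest expression by start distance must win
  probs <- rbind(
    c(0.2, 0.4, 0.2, 0.2),
    c(0.2, 0.4, 0.2, 0.2),
    c(0.2, 0.4, 0.2, 0.2),
    c(0.1, 0.7, 0.1, 0.1)
  )
  sel <- select_index(fx_pred_pairs(note, probs), list(note))
  m1 <- sel[sel$me_id == "m1", ]
  d <- function(te) abs(note$temporal_expressions$start[
    note$temporal_expressions$te_id == te] - note$entities$start[1])
  dists <- sapply(c("t0", "t1", "t2"), d)
  expect_equal(m1$te_id, names(which.min(dists)))
  expect_equal(m1$relation, "SIMULTANEOUS")
  # exact tie in probability and distance falls back to candidate order
  note2 <- fixture_note(gold_m1 = 3L, gold_m2 = 1L)
  probs2 <- probs
  sel2 <- select_index(fx_pred_pairs(note2, probs2)[4, ], list(note2))
  expect_equal(sel2$te_id, "t0")
  expect_error(select_index(fx_pred_pairs(note, probs)[0, ], list(note)),
               class = "medtimeline_select_error")
})

test_that("micro P/R/F1 are exact on a written-out 10-pair confusion fixture", {
  # gold:      S S S B B A N N N N
  # predicted: S B S B N A S N N B
  # non-NONE predicted = 7? -> S,B,S,B,A,S,B = 7; correct non-NONE = S,S,B,A = 4
  # gold non-NONE = 6
  key <- tibble::tibble(note_id = "n", me_id = paste0("m", 1:10),
                        te_id = "t1")
  gold <- key; gold$relation <- c("SIMULTANEOUS", "SIMULTANEOUS", "SIMULTANEOUS",
                                  "BEFORE", "BEFORE", "AFTER",
                                  "NONE", "NONE", "NONE", "NONE")
  pred <- key; pred$relation <- c("SIMULTANEOUS", "BEFORE", "SIMULTANEOUS",
                                  "BEFORE", "NONE", "AFTER",
                                  "SIMULTANEOUS", "NONE", "NONE", "BEFORE")
  out <- relation_prf(gold, pred)
  expect_equal(out$precision, 4 / 7)
  expect_equal(out$recall, 4 / 6)
  expect_equal(out$f1, 2 * (4 / 7) * (4 / 6) / (4 / 7 + 4 / 6))
  # perfect predictions
  perfect <- relation_prf(gold, gold)
  expect_equal(perfect, list(precision = 1, recall = 1, f1 = 1))
  # all-NONE predictions: recall 0, precision defined as 0
  none <- key; none$relation <- "NONE"
  degenerate <- relation_prf(gold, none)
  expect_equal(degenerate, list(precision = 0, recall = 0, f1 = 0))
  # universe mismatch rejected
  expect_error(relation_prf(gold[1:9, ], pred),
               class = "medtimeline_eval_error")
})

test_that("relaxed credits the right expression, strict the right ID", {
  note <- fixture_note(gold_m1 = 2L, gold_m2 = 1L)  # m1 on an interval
  tl <- build_timeline(note)
  # prediction for m1: chose t1 (node 3? no - t1 is node 3 on this timeline)
  # timeline: t0 -> 1, t1 -> 3, t2 -> 5; gold 2 lies between t0 and t1
  preds <- tibble::tibble(
    note_id = "fx1", me_id = c("m1", "m2"),
    te_id = c("t1", "t0"),
    relation = c("SIMULTANEOUS", "SIMULTANEOUS"),
    confidence = 1,
    pred_index = c(relation_to_index("t1", "SIMULTANEOUS", tl), 1L)
  )
  acc <- indexing_accuracy(list(note), preds)
  # m1: strict wrong (3 != 2) but t1 is adjacent to interval 2 -> relaxed
  expect_equal(acc$strict, 0.5)
  expect_equal(acc$relaxed, 1)
  et <- error_taxonomy(list(note), preds)
  expect_equal(et$type_errors, 1L)
  expect_equal(et$selection_errors, 0L)
})

test_that("node/interval breakdown matches hand computation", {
  # 4 entities: 3 gold nodes (1, 3, 3) + 1 gold interval (2);
  # one node entity mispredicted to an interval
  note <- timeline_note(c("2012-01-02", "2012-01-06"))
  note$entities <- tibble::tibble(
    me_id = paste0("m", 1:4), start = 0L, end = 1L,
    gold_index = c(1L, 3L, 3L, 2L), surface = "x")
  note$sections <- tibble::tibble(name = "Other", start = 0L,
                                  end = nchar(note$text),
                                  anchor = "admission",
                                  anchor_relation = "Simultaneous")
  preds <- tibble::tibble(
    note_id = "tl1", me_id = paste0("m", 1:4),
    te_id = c("t1", "t2", "t1", "t1"),
    relation = c("SIMULTANEOUS", "SIMULTANEOUS", "AFTER", "AFTER"),
    confidence = 1,
    pred_index = c(1L, 3L, 2L, 2L))
  bk <- breakdown_by_kind(list(note), preds)
  # predicted nodes: m1, m2 (both strictly right) -> node P = 2/2
  # gold nodes: m1, m2, m3 -> node R = 2/3
  expect_equal(bk$node$precision, 1)
  expect_equal(bk$node$recall, 2 / 3)
  # predicted intervals: m3 (wrong: gold 3), m4 (right: gold 2)
  expect_equal(bk$interval$precision, 1 / 2)
  expect_equal(bk$interval$recall, 1)
  # everything-node degenerate case
  preds2 <- preds
  preds2$pred_index <- c(1L, 3L, 3L, 1L)
  preds2$te_id <- c("t1", "t2", "t2", "t1")
  note2 <- note
  note2$entities$gold_index <- c(1L, 3L, 3L, 1L)
  bk2 <- breakdown_by_kind(list(note2), preds2)
  expect_equal(bk2$node$precision, 1)
  expect_equal(bk2$node$recall, 1)
  expect_equal(bk2$interval$precision, 0)
  expect_equal(bk2$interval$recall, 0)
})

test_that("selection and type errors partition the strict errors", {
  note <- fixture_note(gold_m1 = 3L, gold_m2 = 1L)
  tl <- build_timeline(note)
  # m1: entirely wrong expression (t2, node 5, far from gold 3) -> selection
  # m2: right expression, wrong relation -> type
  preds <- tibble::tibble(
    note_id = "fx1", me_id = c("m1", "m2"),
    te_id = c("t2", "t0"),
    relation = c("SIMULTANEOUS", "AFTER"),
    confidence = 1,
    pred_index = c(5L, 2L))
  et <- error_taxonomy(list(note), preds)
  expect_equal(et$selection_errors, 1L)
  expect_equal(et$type_errors, 1L)
  expect_equal(et$strict_errors, 2L)
})

test_that("metric invariants hold on random prediction sets", {
  co <- shared_corpus()[1:5]
  set.seed(77)
  notes <- setNames(unclass(co), sapply(co, `[[`, "note_id"))
  for (trial in 1:5) {
    preds <- purrr::map_dfr(co, function(note) {
      tl <- build_timeline(note)
      purrr::map_dfr(note$entities$me_id, function(me_id) {
        te <- sample(note$temporal_expressions$te_id, 1)
        rel <- sample(c("SIMULTANEOUS", "BEFORE", "AFTER"), 1)
        tibble::tibble(note_id = note$note_id, me_id = me_id, te_id = te,
                       relation = rel, confidence = runif(1),
                       pred_index = relation_to_index(te, rel, tl))
      })
    })
    acc <- indexing_accuracy(co, preds)
    expect_lte(acc$strict, acc$relaxed)
    et <- error_taxonomy(co, preds)
    n <- nrow(as_tibble(co))
    expect_equal(et$selection_errors + et$type_errors, et$strict_errors)
    expect_equal(et$strict_errors + round(acc$strict * n), n)
    bk <- breakdown_by_kind(co, preds)
    for (kind in bk) {
      for (v in kind) { expect_gte(v, 0); expect_lte(v, 1) }
    }
  }
})

test_that("the evaluation report bundles, prints and tidies consistently", {
  note <- fixture_note(gold_m1 = 3L, gold_m2 = 1L)
  probs <- rbind(
    c(0.9, 0.02, 0.04, 0.04),
    c(0.1, 0.7, 0.1, 0.1),
    c(0.6, 0.1, 0.2, 0.1),
    c(0.1, 0.7, 0.1, 0.1))
  pp <- fx_pred_pairs(note, probs)
  sel <- select_index(pp, list(note))
  rep <- evaluate_indexing(list(note), sel, pp, method = "demo")
  expect_s3_class(rep, "mt_eval_report")
  expect_equal(rep$strict, 1)
  expect_equal(rep$relaxed, 1)
  td <- tidy(rep)
  expect_equal(td$strict, 1)
  expect_equal(td$method, "demo")
  expect_equal(td$selection_errors + td$type_errors, 0)
  expect_output(print(rep), "strict")
  gl <- glance(rep)
  expect_equal(gl$n_entities, 2L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
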