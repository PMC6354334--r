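test_that("a minimal valid note resolves all references", {
  note <- fixture_note()
  expect_s3_class(note, "clinical_note")
  expect_equal(note$entities$surface, c("发热", "水肿"))
  expect_equal(note$temporal_expressions$surface[2], "2011-10-09")
  expect_equal(note$admission_te, "t0")
  expect_silent(validate_note(note))
})

test_that("validation rejects spans that violate the invariants", {
  note <- fixture_note()
  bad <- note
  bad$entities$end[1] <- nchar(note$text) + 10L
  expect_error(validate_note(bad), "out of bounds",
               class = "medtimeline_validation_error")
  # entity span crossing a section boundary
  bad <- note
  bad$entities$start[2] <- note$sections$start[3] - 2L
  expect_error(validate_note(bad), "crosses a section",
               class = "medtimeline_validation_error")
  bad <- note
  bad$admission_te <- "nonexistent"
  expect_error(validate_note(bad), "does not refer",
               class = "medtimeline_validation_error")
})

test_that("write_notes / read_notes round-trip is the identity", {
  corpus <- generate_corpus(4, seed = 21)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_notes(corpus, f1)
  back <- read_notes(f1)
  write_notes(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(length(back), length(corpus))
  for (i in seq_along(corpus)) {
    expect_equal(back[[i]]$text, corpus[[i]]$text)
    expect_equal(back[[i]]$entities, corpus[[i]]$entities)
    expect_equal(back[[i]]$temporal_expressions,
                 corpus[[i]]$temporal_expressions)
  }
})

test_that("malformed corpus files are rejected with line information", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c("{\"note_id\": \"a\""), f)
  expect_error(read_notes(f), "line 1", class = "medtimeline_parse_error")
  writeLines("{\"note_id\": \"a\", \"text\": \"x\"}", f)
  expect_error(read_notes(f), "missing field",
               class = "medtimeline_parse_error")
})

test_that("a file whose entity crosses a section boundary fails validation", {
  note <- fixture_note()
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_notes(list(note), f)
  doc <- jsonlite::fromJSON(readLines(f, warn = FALSE), simplifyVector = FALSE)
  doc$entities[[2]]$start <- doc$sections[[3]]$start - 2L
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null")), f)
  expect_error(read_notes(f), "crosses",
               class = "medtimeline_validation_error")
})

test_that("sentence segmentation splits on terminators, attaches them left", {
  txt <- "甲发热。乙头痛！丙咳嗽"
  note <- clinical_note("s1", txt,
    sections = tibble::tibble(name = "Other", start = 0L, end = nchar(txt)),
    entities = tibble::tibble(me_id = character(), start = integer(), end = integer()),
    temporal_expressions = tibble::tibble(te_id = character(), start = integer(),
                                          end = integer(), value = character(),
                                          kind = character()))
  s <- segment_sentences(note)
  expect_equal(nrow(s), 3)
  expect_equal(substr(txt, s$start[1] + 1, s$end[1]), "甲发热。")
  expect_equal(substr(txt, s$start[2] + 1, s$end[2]), "乙头痛！")
  expect_equal(substr(txt, s$start[3] + 1, s$end[3]), "丙咳嗽")
  # spans tile the section
  expect_equal(s$start, c(0L, head(s$end, -1)) |> as.integer())
  expect_equal(tail(s$end, 1), nchar(txt))
})

test_that("a section without terminators is one sentence", {
  note <- fixture_note()
  s <- segment_sentences(note)
  sec2 <- which(s$section == 3)
  expect_length(sec2, 1)
  expect_equal(s$start[sec2], note$sections$start[3])
  expect_equal(s$end[sec2], note$sections$end[3])
})

test_that("splitting never cuts an annotated span (oracle comparison)", {
  # TE surface contains a terminator-like character
  txt <- "于2011；9；13诊断为发热。随访正常。"
  te_start <- 1L; te_end <- 10L   # "2011；9；13"
  note <- clinical_note("s2", txt,
    sections = tibble::tibble(name = "Other", start = 0L, end = nchar(txt)),
    entities = tibble::tibble(me_id = "m1", start = 13L, end = 15L),
    temporal_expressions = tibble::tibble(te_id = "t1", start = te_start,
                                          end = te_end, value = "2011-09-13",
                                          kind = "other"))
  s <- segment_sentences(note)
  # brute-force oracle: split at every terminator, then re-merge any split
  # inside an annotated span
  terms <- c("。", "！", "？", "；", "?", "!", ";", "\n")
  chars <- strsplit(txt, "")[[1]]
  breaks <- which(chars %in% terms)
  breaks <- breaks[!(breaks > te_start & breaks < te_end)]  # 0-based half-open
  expected_ends <- sort(unique(c(breaks, nchar(txt))))
  expect_equal(s$end, expected_ends)
  # TE span intact inside one sentence
  i <- which(s$start <= te_start & te_end <= s$end)
  expect_length(i, 1)
})

test_that("the timeline numbers nodes oddly and intervals evenly", {
  note <- timeline_note(c("2011-10-09", "2011-10-13"))
  tl <- build_timeline(note)
  expect_equal(tl$nodes$node_id, c(1L, 3L))
  expect_equal(timeline_ids(tl), c(0L, 1L, 2L, 3L, 4L))
  expect_equal(te_node_id(tl, "t1"), 1L)
  expect_equal(te_node_id(tl, "t2"), 3L)
  # degenerate note: no TEs -> single interval 0
  expect_equal(timeline_ids(build_timeline(timeline_note(character()))), 0L)
})

test_that("TEs sharing a normalized value merge into one node", {
  note <- timeline_note(c("2011-10-09", "2011-10-13", "2011-10-09"))
  tl <- build_timeline(note)
  expect_equal(tl$n_nodes, 2L)
  expect_equal(timeline_ids(tl), 0:4)
  expect_setequal(tl$nodes$te_ids[[1]], c("t1", "t3"))
  expect_equal(te_node_id(tl, "t3"), 1L)
})

test_that("ID sets are exactly {0..2n} for all n <= 5, with and without duplicates", {
  pool <- sprintf("2012-03-%02d", 1:5)
  set.seed(42)
  for (n in 1:5) {
    for (rep in 1:8) {
      vals <- sample(pool, n, replace = TRUE)
      tl <- build_timeline(timeline_note(vals))
      expect_identical(timeline_ids(tl), brute_force_timeline_ids(vals))
      expect_false(is.unsorted(tl$nodes$value, strictly = TRUE))
    }
  }
})

test_that("relation_to_index follows the numbering scheme and rejects NONE", {
  note <- timeline_note(c("2011-10-09", "2011-10-13"))
  tl <- build_timeline(note)
  expect_equal(relation_to_index("t2", "SIMULTANEOUS", tl), 3L)
  expect_equal(relation_to_index("t1", "BEFORE", tl), 0L)
  expect_equal(relation_to_index("t1", "AFTER", tl), 2L)
  expect_error(relation_to_index("t1", "NONE", tl),
               class = "medtimeline_timeline_error")
})

test_that("gold_relation_for_pair matches the definition on enumerated cases", {
  note <- timeline_note(c("2012-01-01", "2012-01-05"))
  tl <- build_timeline(note)
  expect_equal(gold_relation_for_pair(1L, "t1", tl), "SIMULTANEOUS")
  # interval 2 lies between the two nodes: AFTER for t1, BEFORE for t2
  expect_equal(gold_relation_for_pair(2L, "t1", tl), "AFTER")
  expect_equal(gold_relation_for_pair(2L, "t2", tl), "BEFORE")
  expect_equal(gold_relation_for_pair(4L, "t1", tl), "NONE")
  expect_error(gold_relation_for_pair(NA, "t1", tl),
               class = "medtimeline_timeline_error")
})

test_that("relation_to_index and gold_relation_for_pair are mutually inverse", {
  for (n in 1:5) {
    note <- timeline_note(sprintf("2012-03-%02d", seq_len(n)))
    tl <- build_timeline(note)
    for (te in note$temporal_expressions$te_id) {
      for (rel in c("SIMULTANEOUS", "BEFORE", "AFTER")) {
        id <- relation_to_index(te, rel, tl)
        expect_equal(gold_relation_for_pair(id, te, tl), rel)
      }
      # and back: every non-NONE gold label round-trips to its index
      for (gold in timeline_ids(tl)) {
        rel <- gold_relation_for_pair(gold, te, tl)
        if (rel != "NONE") {
          expect_equal(relation_to_index(te, rel, tl), gold)
        }
      }
    }
  }
})

test_that("the convenience date parser handles its three forms only", {
  expect_equal(parse_time_value("2011-9-13"), "2011-09-13")
  expect_equal(parse_time_value("2011年10月9日"), "2011-10-09")
  expect_equal(parse_time_value("4天前", "2012-02-03"), "2012-01-30")
  expect_true(is.na(parse_time_value("去年十月")))
  expect_true(is.na(parse_time_value("4天前")))  # no admission anchor
})
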