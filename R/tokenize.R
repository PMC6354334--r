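# Default tokenization: character-level for Chinese with ASCII alphanumeric
# runs kept whole ("2011" is one token); whitespace is dropped. The annotated
# target span (entity or temporal expression) collapses to a single token so
# the encoder always has one target word.

tokenize_chars <- function(s) {
  if (!nzchar(s)) return(character(0))
  unlist(stringr::str_extract_all(s, "[A-Za-z0-9]+|[^\\sA-Za-z0-9]"))
}

# tokens + 1-based target index for a sentence holding one target span;
# offsets are relative to the sentence start
tokenize_with_target <- function(sentence_text, target_start, target_end) {
  pre <- substr(sentence_text, 1, target_start)
  target <- substr(sentence_text, target_start + 1, target_end)
  post <- substr(sentence_text, target_end + 1, nchar(sentence_text))
  pre_toks <- tokenize_chars(pre)
  list(tokens = c(pre_toks, target, tokenize_chars(post)),
       k = length(pre_toks) + 1L)
}

# truncate to a max_len window centred on the target; returns tokens, k and
# clipped signed offsets t - k
window_and_positions <- function(tokens, k, max_len) {
  n <- length(tokens)
  if (n > max_len) {
    start <- min(max(k - (max_len - 1L) %/% 2L, 1L), n - max_len + 1L)
    tokens <- tokens[start:(start + max_len - 1L)]
    k <- k - start + 1L
    n <- max_len
  }
  clip <- max_len - 1L
  pos <- pmin(pmax(seq_len(n) - k, -clip), clip)
  list(tokens = tokens, k = k, positions = pos)
}

# encodings for the entity sentence and expression sentence of every pair;
# tokens stay strings here, ids are resolved against a vocabulary later
pair_sentence_encodings <- function(pairs, corpus, max_len) {
  notes <- stats::setNames(unclass(corpus) , vapply(corpus, `[[`, character(1), "note_id"))
  sent_cache <- lapply(notes, segment_sentences)
  enc_one <- function(note, sentences, start, end) {
    si <- sentence_of_span(sentences, start, end)
    if (is.na(si)) {
      abort(sprintf("note '%s': span [%d,%d) not inside one sentence",
                    note$note_id, start, end),
            class = "medtimeline_feature_error")
    }
    s0 <- sentences$start[si]
    sent_text <- substr(note$text, s0 + 1, sentences$end[si])
    tk <- tokenize_with_target(sent_text, start - s0, end - s0)
    window_and_positions(tk$tokens, tk$k, max_len)
  }
  me_enc <- vector("list", nrow(pairs))
  te_enc <- vector("list", nrow(pairs))
  fvs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    note <- notes[[pairs$note_id[i]]]
    sentences <- sent_cache[[pairs$note_id[i]]]
    me <- note$entities[note$entities$me_id == pairs$me_id[i], ]
    te <- note$temporal_expressions[note$temporal_expressions$te_id == pairs$te_id[i], ]
    me_enc[[i]] <- enc_one(note, sentences, me$start, me$end)
    te_enc[[i]] <- enc_one(note, sentences, te$start, te$end)
    fvs[[i]] <- extract_relation_features(pairs$me_id[i], pairs$te_id[i],
                                          note, sentences)
  }
  list(me = me_enc, te = te_enc, features = fvs)
}

build_vocab <- function(encodings) {
  toks <- unique(unlist(c(lapply(encodings$me, `[[`, "tokens"),
                          lapply(encodings$te, `[[`, "tokens"))))
  c("[PAD]", "[UNK]", sort(toks))
}

token_ids <- function(tokens, vocab) {
  ids <- match(tokens, vocab)
  ids[is.na(ids)] <- 2L  # [UNK]
  ids
}
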