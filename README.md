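# medtimeline

Temporal indexing of medical entities in section-structured (Chinese)
clinical notes: every annotated problem, test or treatment is placed on a
per-note timeline built from the note's temporal expressions.

## The problem

A clinical note mentions a handful of explicit times. Sorted by normalized
value (mentions sharing a value merged), they become *time nodes* with odd
IDs 1, 3, ..., 2n−1; the gaps around them are *time intervals* with even IDs
0, 2, ..., 2n. Temporal indexing assigns each medical entity (ME) one
timeline ID — the time it happened, or the interval it happened in. The
package solves this as a three-stage pairwise selection problem:

1. **Candidate selection** — an entity's candidate times are its section's
   anchor time (admission or discharge, per the standard section inventory)
   plus all temporal expressions (TEs) in its section.
2. **Relation classification** — each (ME, TE) pair is classified as
   `NONE`, `SIMULTANEOUS`, `BEFORE` or `AFTER`, where `BEFORE`/`AFTER` index
   the first interval before/after the TE. The main classifier is an
   RNN-CNN: character-level word + position embeddings feed a peephole
   bidirectional LSTM, a bank of width-3/5/7 sigmoid convolution filters
   with max-pooling builds one representation per sentence, and a softmax
   layer fuses both sentence representations with ten embedded hand-crafted
   features:

   *Y* = softmax(*W*·[*C*<sub>M</sub>, *C*<sub>T</sub>, *Z*] + *b*)

   CNN-only and RNN-only ablations, a section-rule baseline, a linear-SVM
   baseline, and a probability-averaging ensemble ("merged") are included.
3. **Index selection** — per entity, the highest-confidence
   (candidate, non-NONE relation) wins and maps to a timeline ID.

Evaluation follows the matching protocol: micro precision/recall/F1 over
pairs, relaxed (right TE) and strict (right timeline ID) accuracy,
node-vs-interval breakdowns, and a selection-vs-type error taxonomy.

Clinical corpora of this kind are protected, so the package ships a seeded
synthetic-note generator that emulates their sectional structure and
annotation statistics (~22 MEs and ~7 TEs per note, 68/32 node/interval
gold mix) with gold indices recoverable by construction — every stage is
testable end to end without any real data. The neural network (including
the peephole recurrence and its full backward pass) is implemented in
RcppArmadillo and gradient-checked against finite differences.

## A worked example

```r
library(medtimeline)

corpus <- generate_corpus(80, seed = 7)   # synthetic section-structured notes
train  <- corpus[1:60]
test   <- corpus[61:80]

coverage_report(test)
#> Candidate selection coverage
#>   entities           439
#>   covered            439
#>   coverage           1.0000
#>   selected pairs     1155
#>   mean candidates    2.63

model <- train_relation_model(train, model_config(epochs = 5), seed = 1)
pairs <- predict(model, test)             # one row per (ME, TE) pair + 4 probabilities
preds <- select_index(pairs, test)        # one timeline ID per entity
evaluate_indexing(test, preds, pairs, method = "rnn-cnn")
#> Temporal indexing evaluation - rnn-cnn (439 entities)
#>   relation      P  91.34%  R  90.32%  F1  90.83%
#>   indexing      relaxed 100.00%  strict  91.34%
#>   node          P  88.72%  R 100.00%  F1  94.03%
#>   interval      P 100.00%  R  72.86%  F1  84.30%
#>   errors        selection 0  type 38
```

Reading the output: every candidate set contained the gold time
(coverage 1 — the generator's noise-free guarantee); after five epochs the
network already selects the right TE for every entity (relaxed 100%) and the
right timeline ID for 91.3% (strict); its remaining mistakes are all type
errors — right expression, wrong relation — concentrated on interval
entities, the same asymmetry the method family shows on real notes. Twenty
epochs (the default) push held-out strict accuracy above 0.95.

The rule and SVM baselines and the ensemble run the same way:

```r
rule  <- rule_based_index(test)                      # no training needed
svm   <- train_svm_model(train)
merged <- merge_predictions(list(pairs, predict(svm, test)))
evaluate_indexing(test, select_index(merged, test), merged, method = "merged")
```

`autoplot()` and `tidy()` work on models (loss curves) and reports; a thin
CLI lives at `inst/cli/medtimeline.R`
(`generate | train | predict | evaluate`). Corpora are JSON-lines files
(`read_notes()` / `write_notes()` round-trip exactly); word2vec text-format
embeddings can initialize the word table.

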