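---
title: "Temporal indexing of medical entities: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal indexing of medical entities: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtimeline)
```

## The task

Chinese clinical notes describe a patient's problems, tests and treatments
relative to a handful of explicit dates. *Temporal indexing* places every
annotated medical entity (ME) on a per-note timeline built from the note's
temporal expressions (TEs): the TEs, sorted by normalized value and merged
when they share a value, become *time nodes* with odd IDs 1, 3, ..., 2n-1,
and the gaps around them become *time intervals* with even IDs 0, 2, ..., 2n
(0 before the first node, 2n after the last). Every entity receives exactly
one timeline ID.

The package treats this as a three-stage pairwise selection problem:

1. **Candidate selection.** Notes follow a fixed sectional skeleton, and each
   section has a characteristic anchor time: contents of a history section
   happened *before admission*, a physical examination is *at admission*, a
   discharge summary is *at discharge* (see `section_anchor_table()`). The
   candidate times of an entity are its section's anchor TE plus all TEs
   inside the section. This keeps the pair universe small and nearly always
   contains the right time.
2. **Pairwise relation classification.** Every (entity, candidate) pair gets
   one of four labels: `SIMULTANEOUS` (the TE's node is the entity's time),
   `BEFORE` / `AFTER` (the first interval before/after the TE), or `NONE`.
   Note that an entity indexed to an interval yields *two* positive pairs —
   `AFTER` for the node below it and `BEFORE` for the node above.
3. **Index selection.** Over all (candidate, non-NONE relation) scores of an
   entity, the highest probability wins; ties break towards the nearer TE,
   then candidate order. `relation_to_index()` converts the winner into a
   timeline ID.

## The RNN-CNN relation classifier

For each pair the classifier encodes two sentences — the entity's and the
expression's — and a vector of ten hand-crafted features.

**Input layer.** Sentences are tokenized character-wise (ASCII alphanumeric
runs stay whole, so `2011` is one token) and the annotated target span is
collapsed to a single token, giving each sentence one target word at index
$k$. Token $t$ is represented as $x_t = [E_w \vec w_t, E_d \vec d_t]$, the
concatenation of a 50-dimensional word embedding and a 30-dimensional
embedding of the signed offset $d_t = t - k$. Offsets are clipped to
$\pm(\text{max len}-1)$; sentences longer than 100 tokens are truncated to a
window centred on the target. Position embeddings and feature embeddings are
initialized uniformly in $[-1, 1]$; word embeddings likewise, unless a
word2vec text-format table is supplied (`read_word2vec()`).

**Peephole BiLSTM.** Each direction runs an LSTM whose gates also see the
cell state:
$$i_t = \sigma(W_{xi} x_t + W_{hi} h_{t-1} + W_{ci} c_{t-1} + b_i)$$
$$f_t = \sigma(W_{xf} x_t + W_{hf} h_{t-1} + W_{cf} c_{t-1} + b_f)$$
$$c_t = f_t \otimes c_{t-1} + i_t \otimes \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)$$
$$o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} c_t + b_o)$$
$$h_t = o_t \otimes \tanh(c_t)$$
with $h_t = [h_{ft}, h_{bt}]$ the concatenation of both directions (50 units
each). The peephole terms are implemented as full $h \times h$ matrices —
the literal reading of the equations; the common diagonal convention is a
special case. Because no pre-installed package provides peephole cells, the
recurrence and its complete backward pass are hand-written (RcppArmadillo),
and every layer is verified against finite-difference gradients in the test
suite.

**Convolution and max-pooling.** Filters of widths 3/5/7 slide over the
LSTM output; window $j$ of filter $W^{(i)}$ yields
$C^{(i)}_j = \sigma(W^{(i)} \otimes H_{[j:j+k-1]} + b^{(i)})$ — a sigmoid, as
the architecture specifies, not a ReLU — and max-pooling keeps one value per
filter. The pooled values concatenate into the sentence representation.

**Output layer.** $Y = \mathrm{softmax}(W_o [C_M, C_T, Z] + b_o)$, where
$Z$ concatenates the ten embedded relation features (10 × 20 = 200 wide).
Dropout (p = 0.5) is applied to $[C_M, C_T, Z]$ during training; where
dropout sits was an open choice, and before the only fully-connected layer
is the standard placement.

**Ablation variants.** `variant = "cnn"` convolves the raw input
representations directly; `variant = "rnn"` replaces the convolution by the
concatenated final states of the two directions.

### Hyper-parameters and open choices

| parameter | default | note |
|---|---|---|
| word / position / feature dims | 50 / 30 / 20 | published configuration |
| LSTM units per direction | 50 | |
| filter widths | 3 / 5 / 7 | |
| convolution filters | 100 total (34/33/33) | see below |
| max sentence length | 100 tokens | |
| dropout | 0.5 | training only |
| batch size / epochs | 32 / 20 | plain SGD, cross-entropy |
| learning rate | 0.1, constant | not in the published table; package default, logged per run |

The published filter count ("100 convolution filters" next to "size 3/5/7")
can be read as 100 per width or 100 in total. We implement the literal
total-count reading, split as evenly as possible across widths, and expose
`conv_filters` so either reading is one argument away.

Other choices that the architecture leaves open, decided here once:

* **Targets spanning several tokens** collapse to a single vocabulary item,
  since the input layer assumes a single target word.
* **Out-of-vocabulary tokens** at prediction time map to `[UNK]`, whose
  vector is the mean of all trained word vectors — deterministic and
  standard.
* **Masking.** Padding steps carry LSTM state through unchanged and windows
  lying wholly in padding are excluded from pooling, so appending padding
  never changes a prediction (property-tested to 1e-6).
* **Weight initialization** beyond the embeddings is not specified; dense
  and recurrent weights use a uniform Glorot range, biases start at zero.
* **Feature 10** ("any TE in front of the entity, in its section or
  sentence") is computed at section level, which subsumes the sentence-level
  reading; the pair's own TE counts toward features 5/6/10 when it lies in
  the relevant span, as no exclusion rule is given.
* **Feature 9** gains a `same` category so the function is total when both
  spans share a sentence.

## Baselines and the ensemble

The **rule engine** fires the first matching rule per entity: nearest
preceding TE in the sentence → `SIMULTANEOUS`; else nearest following TE in
the sentence → `SIMULTANEOUS`; else nearest preceding TE in the section →
`SIMULTANEOUS`; else the section anchor with the section's table relation.
The published rule list is explicitly open-ended ("etc."); the two middle
rules make the engine total while reproducing the known failure mode of
rule-based indexing — defaulting to `SIMULTANEOUS` where the true relation
is an interval one. Every decision logs the rule that fired.

The **SVM baseline** uses bags of context words (±5 tokens around each
target) plus the one-hot relation features, in four one-vs-rest linear
machines (`e1071`); class probabilities are the softmax of the four decision
values — chosen over Platt scaling for determinism without an inner CV
split.

The **merged** method averages the class probabilities of the SVM and the
three neural variants per pair, elementwise; the selection step then runs on
the averaged distribution.

## Evaluation protocol

* **Relation micro-P/R/F1** over candidate pairs; positives are the
  non-`NONE` pairs, and `NONE` is excluded from the positive set (standard
  relation-extraction practice; whether it was counted in the original
  protocol is unstated). 0/0 ratios are defined as 0.
* **Strict accuracy**: predicted timeline ID equals the gold ID.
  **Relaxed accuracy**: the chosen TE is right regardless of relation type —
  for an interval gold, an interval has no TE of its own, so "right TE" is
  read as *adjacent to the gold interval*. Strict never exceeds relaxed.
* **Node/interval breakdown**: precision over entities predicted to
  odd/even IDs, recall over gold odd/even IDs, strict hits only.
* **Error taxonomy**: strict errors split into *selection errors* (wrong TE)
  and *type errors* (right TE, wrong relation); the two partition the strict
  errors by construction.

## The synthetic-note generator

Real clinical corpora of this kind are protected, so the package ships a
seeded generator (`generate_corpus()`) whose defaults emulate the published
corpus statistics: ~22 entities and ~7 TE mentions per note, the standard
section inventory, and a 68/32 split of node vs interval gold indices.
Every entity is planted by a positional template whose surface pattern
determines its relation:

* `于{date}出现{entity}` — the date governs the entity: `SIMULTANEOUS`;
* `于{date}行{...}，术后出现{entity}` — a dated event with a
  "post-operatively" connective: `AFTER`;
* `{entity}出现于{date}之前` — an explicit "before" construction: `BEFORE`;
* an entity in a sentence without any date inherits its section's anchor
  relation (e.g. past medical history → `BEFORE` admission).

History dates fall strictly before admission and in-stay dates strictly
between admission and discharge, `BEFORE` templates attach only to the
earliest history date and `AFTER` templates only to the latest history or
in-stay date, so each planted gold index is derivable from its own sentence
pattern and section — the generator's patterns are learnable by design. A
manifest records every planted template, so oracle tests re-derive gold
indices without re-parsing text. The `label_noise` parameter re-plants a
fraction of gold indices to IDs unreachable from the entity's candidate set,
giving coverage `1 - noise` in expectation for coverage tests; the default
is 0.

What the generator does *not* emulate: real lexical variety (its prose is
templated pseudo-Chinese around a small vocabulary), ambiguous or implicit
time anchoring (the "one day ago whose baseline shifted" problem that makes
real annotation hard), normalization errors, and cross-section semantics.
Passing the learnability tests therefore shows that the machinery — data
model, features, network, training, selection, metrics — is correct and that
the architecture can exploit positional and lexical cues; it does not show
that the published accuracy transfers to real notes, which is exactly why
the original headline numbers are not reproduction targets here.

## Numerical and testing choices

* Gradients of every layer (embeddings, both LSTM directions, every filter
  bank, output layer) are checked against central finite differences at
  tolerance 1e-4 on small random instances.
* The LSTM and convolution forward passes are checked against independent
  step-by-step oracles written in plain R.
* Training under a fixed seed is bit-reproducible on one platform
  (initialization, shuffling and dropout all draw from R's RNG);
  length-bucketed shuffling keeps padding tight without breaking
  determinism.
* Softmax subtracts the column maximum; cross-entropy clamps probabilities
  at 1e-12.
* Problem sizes used by the shipped checks: the held-out learnability check
  trains on 300 synthetic notes and evaluates on 100 (generation seed 7,
  noise 0, default configuration); `scripts/acceptance.R` runs the full
  six-method comparison on a 150/50 split, sizes chosen so the whole
  pipeline (four trained classifiers plus ensemble) completes comfortably on
  one CPU.

## Known limitations

* TE recognition and full normalization are out of scope: entities and
  normalized values arrive annotated; only a convenience parser for
  `YYYY-MM-DD`, `YYYY年MM月DD日` and `X天前` (against the admission date) is
  provided.
* Cross-note timelines, discontinuous spans and calendar arithmetic beyond
  ordering are not modelled.
* The SVM bundle wraps `e1071` model objects and is not file-serialized by
  the CLI.
* Whether a twice-mentioned TE with one value received one or two IDs in the
  original annotation is not documented; mentions sharing a value merge into
  one node here, which keeps node IDs unique per time point.
* The interval after the last TE is assumed annotatable (ID 2n); entities
  occurring after the last mentioned time need it.
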