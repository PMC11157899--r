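---
title: "Multi-task modifier classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task modifier classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmtl)
```

## The task and the model

Given a document, a gold entity span set (possibly discontiguous), and a
*modifier schema* — an ordered list of modifier types, each with a label
vocabulary and a designated default ("unmarked") label — the task is to
predict one label per modifier for every mention. The package treats this
as multi-task classification over a shared representation:

1. **Featurization.** Each mention becomes a sequence pair. The left
   sequence is the document substring from 200 characters before the first
   span to 50 characters after the last span, clipped at document
   boundaries; the entity sequence is the mention surface (fragments of a
   discontiguous mention joined by one space), or empty in the "no hint"
   ablation. The asymmetric window reflects where modifier cues live in
   clinical prose: mostly before the mention. No sentence segmentation is
   used anywhere — clinical notes routinely lack well-formed sentence
   boundaries, and a character window needs none.
2. **Encoding.** A `PairEncoder` maps the pair to a pooled vector
   `h` of fixed dimension H. The encoder is pluggable behind five S4
   generics (`encoderPrepare`, `encoderForward`, `encoderBackward`,
   `encoderParams`, `encoderWithParams`); anything honoring the contract,
   from the bundled compact encoder to an externally served pretrained
   clinical transformer, can drive the same heads, losses, and training
   loop.
3. **Heads.** One linear-softmax head per schema modifier, in schema
   order, all fed the same pooled vector: `P(y_i | x) = softmax(W_i h +
   b_i)`. Single-task models are the one-head special case
   (`makeSingleTaskModels`), trained separately per modifier with fresh
   encoders.
4. **Loss.** Per head, the batch mean of `−log p(gold)`; the multi-task
   loss is the plain arithmetic mean over heads. The focal variant
   `−(1 − p)^γ log p` (γ = 2 by default, the canonical choice; no class
   weighting term) is available for the heavy default-class imbalance.
   We use the batch *mean* rather than a batch sum so that the loss scale
   is invariant to batch size; the mean over heads makes head count
   equally immaterial.

## Training

`trainModel` runs AdamW — decoupled weight decay applied to weight
matrices, not biases — over encoder and heads jointly. Defaults in
`trainConfig` (learning rate 2e-5, weight decay 1e-2, batch 64, at most 10
epochs, token budget 144) are the standard fine-tuning recipe for a large
pretrained encoder. The bundled compact encoder is trained *from scratch*,
where 2e-5 is far too small; `tinyTrainConfig` substitutes 3e-2, chosen for
stable convergence of the small parameterization at desk scale, and leaves
everything else alone.

**Early stopping.** After each epoch the development-set unweighted
accuracy, macro-averaged over heads, is computed; training stops when it
fails to strictly improve for `patience` (default 3) consecutive epochs,
and the best-scoring epoch's weights are returned. The precise stopping
rule used in prior work on this task is not published in detail; this rule
is our assumption, is labelled as such in the documentation, and is fully
configurable. One consequence worth knowing: accuracy sits at the
default-class plateau (~0.92) for the first epochs while the loss is still
falling, so on very small corpora (≲ 1000 mentions, i.e. ≲ 15 optimizer
steps per epoch) a small patience can stop training before the heads lift
off the plateau. The desk-scale experiments in this package use 2000
mentions, where the plateau is left by epoch ~4.

**Determinism.** All randomness (initialization, epoch shuffles, dropout
masks) derives from the config seed via a fixed child-seed scheme, so
(seed, data, config) determines the trained model exactly; tests assert
bit-identical parameters across repeated runs.

**Final models.** `trainFinal` implements the usual protocol of retraining
on train + dev for the epoch count selected by a prior early-stopped run.

**Token budget.** When a tokenized pair exceeds the 144-token budget
(3 tokens reserved for sequence markers), characters are dropped from the
*left edge of the left sequence* first; the entity sequence is only touched
once the left sequence is exhausted (with a warning). Whether to truncate
left or right is genuinely open; we drop the oldest context because the
mention and its near context carry the cues and the 200/50 window is itself
biased toward preceding text.

## Transfer learning

`transferInit` builds a target-schema model from a source model or
checkpoint: the encoder is copied verbatim; each target modifier whose
*name* matches a source head with an exactly identical label list (and
default index) receives that head's weights verbatim; all other target
heads are freshly initialized; source-only heads are dropped. Matching is
deliberately strict — a name match with a different label list is an error
naming the modifier, because silently copying a head across re-indexed
classes corrupts predictions undetectably. Transferring between the two
built-in schemas yields 5 heads (7-modifier schema → 5-modifier schema)
or 7 (the reverse); the combined-corpus alternative (`mergeCorpora`, union
schema with 9 distinct modifiers, examples carrying defaults for the other
corpus's novel modifiers) trains one model over everything. An alternative
reading of transfer — retaining the union of heads during target
fine-tuning — is possible via `mergeSchemas` + `transferInit`, but the
dropped-heads variant is the default.

Checkpoints keep the encoder in R's native serialization next to a JSON
manifest holding schema, token budget, and head weights keyed by modifier
name (written with 17 significant digits so doubles round-trip
bit-exactly); transfer therefore matches heads by name, never by position.

## Evaluation

* **Weighted accuracy.** Per modifier, class weights are
  `1 − prevalence(class)` with prevalence computed over the *evaluation
  set's gold labels* (as a reference-based scorer does); a flag accepts
  externally supplied weights, e.g. training-set prevalences, for
  sensitivity analysis. The aggregation normalizes by the summed weights of
  the gold labels, so a perfect system scores exactly 1; the alternative
  (normalizing by N) is not used. Single-class gold makes the denominator
  0; the function then returns unweighted accuracy flagged as degenerate.
* **Micro F1** pools TP/FP/FN over non-default classes, treating the
  default as the negative class, the convention under which slot-filling
  F1 is scored; specific classes can be excluded (the mechanism for
  dropping a label with too few test instances). With no non-default gold
  or predictions it is *NA with a note*, never 0.
* **Macro F1** averages per-class F1 with equal weights, optionally
  including the default class (the convention used for corpora reported
  with a null class); classes absent from both gold and predictions are
  skipped with a note.
* **Chi-square.** Pearson on the 2×2 correct/incorrect table, 1 df,
  *without* Yates continuity correction: test sets in this setting number
  hundreds to thousands, where the correction is negligible, and the plain
  statistic is what the comparison calls for. Published accuracies are
  converted to counts by `round(accuracy × N)`. No multiple-testing
  adjustment is applied.
* Cross-modifier averages are simple means over *defined* cells only;
  undefined cells are reported as missing and listed in the report notes.

All four metrics are verified against naive brute-force loop
implementations on ≥1000 randomized prediction sets at tolerance 1e-9.

## The compact encoder

The bundled `tinyEncoder` is trainable token embeddings (case-sensitive
alphanumeric tokenizer, unknown-token bucket), mean-pooled separately over
the left and entity segments, concatenated and projected through one tanh
layer to H = 64. We chose this position-insensitive bag-of-embeddings form
deliberately: modifier cues in this task are short lexical triggers, so
cue detection does not require positional modelling, and a closed-form
backward pass in plain R keeps training a 2000-mention corpus under a few
seconds while remaining exactly reproducible. It is a first-class encoder
honoring the same contract as a transformer binding — not an approximation
of one — but it cannot capture word order, long-range structure, or
subword morphology; conclusions about real clinical text require a real
pretrained clinical encoder behind the same interface. A dropout layer
(rate 0.1, applied to the pooled vector during training) precedes the
heads; whether the reference architecture used one is unstated, so the
rate is configurable and documented as an assumption.

## The synthetic generator

`generateCorpus` produces BRAT-compatible corpora whose statistics mirror
what is reported for real modifier corpora:

* ~92% default prevalence per modifier (binomially verified in tests), with
  per-modifier overrides since real corpora vary by modifier;
* non-default labels realized by cue phrases from a fixed `cueBank` placed
  inside the mention's 200/50 window — before the mention for most
  modifiers, after it for course, matching the window's asymmetry;
* ~4% of examples with a duplicate of the mention inside one window and
  ~2% with three or more occurrences; duplicates share their gold labels so
  that labels remain window-recoverable (real duplicated mentions can
  disagree, distinguishable only by window ends — that ambiguity is
  deliberately *not* reproduced, see below);
* ~5% discontiguous mentions ("fever … ankle" fragments);
* distractor phrases modelled on real confusions — lab-panel
  `Negative`/`Positive` tokens adjacent to an affirmed mention,
  family-history headers, a bare `0` score — that contain no cue phrase and
  must not flip any label;
* documents of several sentences with ≥210 characters of neutral filler
  between mention sentences, so one mention's cues never enter another
  mention's window.

Cue, filler, distractor and entity token inventories are mutually disjoint
(tested), which makes the exact cue-lookup `ruleOracle` score 1.0 on
generated data. That solvability certificate is what makes end-to-end
accuracy a meaningful acceptance surface: a model that fails here fails on
its own.

What the generator does **not** emulate — and hence what passing tests do
not show: real clinical language (negation scope, hedging syntax,
section-dependent semantics), annotation noise and inter-annotator
disagreement, cue ambiguity (the same trigger flipping different modifiers
in context), duplicated mentions with conflicting labels, and realistic
per-modifier prevalences (uniform non-default draw instead). Results on
generated corpora certify the machinery — losses, gradients, transfer
plumbing, metrics — not clinical performance.

## Numerical and convention choices

* Character offsets are 0-based half-open throughout (the BRAT
  convention); R's 1-based `substring` is confined to the I/O layer.
* Unannotated modifiers materialize as the schema default at
  featurization; BRAT output omits default labels, matching how such
  corpora are distributed. A loader flag is unnecessary: explicitly
  annotated default values are also accepted on input.
* Corpus splits are over entity mentions, not documents (a document may
  back mentions in several splits), matching entity-level protocols;
  `byDocument = TRUE` switches to document-level splitting.
* Head initialization: weights N(0, 0.02), zero biases. Embeddings
  N(0, 0.5); projection N(0, 1/sqrt(2D)).
* Probabilities are floored at 1e-12 before `log` (with a warning), so a
  degenerate encoder yields a large finite loss, never `Inf`/`NaN`.
* Argmax decoding breaks exact ties toward the lowest class index —
  deterministic and biased toward the default class, which is listed
  first in the built-in schemas.
* `splitCorpus` sizes are rounded fractions (train, dev) with the
  remainder to test; fractions must sum to 1 within 1e-9.
* A linear learning-rate warmup is available (`warmupFraction`) but off by
  default; no decay schedule is applied.

## Problem sizes

The test suite and the reproduction script run entirely on synthetic data:
2000 mentions for the end-to-end learning experiment (80/10/10 split by
mention), 500–700 mentions per corpus for the transfer-convergence
comparison over 5 seeds, and 15–60 mentions for I/O round-trip and
invariant checks over 20 seeds. These sizes were chosen so the full suite
exercises every claim in about half a minute on one CPU core; they are
stated here so readers know what scale the reported numbers describe.

## Known limitations

* The bundled encoder's bag-of-embeddings pooling cannot represent cue
  scope or order; it is the desk-scale vehicle, not the recommended
  encoder for real notes.
* Named-entity recognition is out of scope: gold entity spans are assumed,
  as in slot-filling evaluations.
* The weighted-accuracy aggregation normalizes by summed gold weights; if
  a comparison target normalizes differently, supply weights explicitly
  and recompute.
* BRAT event (E), relation (R) and normalization (N) lines are ignored;
  only text-bound (T) and attribute (A) lines are interpreted.
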