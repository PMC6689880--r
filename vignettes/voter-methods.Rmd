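---
title: "Methods: a two-stage attention Bi-LSTM-CRF voter for chemical NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage attention Bi-LSTM-CRF voter for chemical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Chemical named entity recognition is cast here as sequence labeling:
documents are tokenized (maximal alphanumeric runs; every other
non-whitespace character is its own single-character token, so offsets of
hyphenated or parenthesized names remain reconstructible), and each token
carries one of 15 IOB labels — `O`, or `B-`/`I-` crossed with the seven
CHEMDNER/CEMP mention subtypes (ABBREVIATION, FAMILY, FORMULA, IDENTIFIER,
MULTIPLE, SYSTEMATIC, TRIVIAL). Entity mentions are recovered from label
runs and evaluated by strict span matching (micro-averaged precision,
recall, F1; subtype-insensitive by default, with a strict mode).

The voter is a stacking ensemble. Stage one is any set of K upstream
taggers; the package deliberately does not wrap specific third-party tools
— their outputs arrive as K extra label columns in the TSV dialect, and a
simulator provides controlled stand-ins. Stage two scores each sentence
with:

1. **Char branch.** Characters are embedded and run through a Bi-LSTM;
   the per-character states are pooled by additive attention,
   `score(s) = v' tanh(W s + b)` softmax-normalized, into one context
   vector per token. Attention pooling (rather than taking the final
   hidden state) lets the model decide which part of a token — prefix,
   suffix, digit cluster — matters.
2. **Word embedding.** Trainable; optionally initialized from a
   word2vec-style text table. No pretrained corpus is assumed.
3. **Stage-one branch.** The K labels are one-hot encoded and concatenated
   (annotator-major blocks of width 15, each block summing to 1). A second
   attention mechanism scores the K·15 components
   (`softmax(W2 tanh(W1 u + b1) + b2)`) and rescales `u` elementwise. The
   same distribution, aggregated per annotator block, is what
   `attention_report()` exposes: a per-token account of how much each
   annotator's vote weighed.
4. A word-level Bi-LSTM over the concatenated representations, a linear
   projection to 15 emission scores, and a **linear-chain CRF** with
   learned transition matrix, trained by exact negative log-likelihood and
   decoded by Viterbi.

The LSTM cells are the peephole variant: input and forget gates
additionally see the previous cell state and the output gate sees the
current one, with diagonal (elementwise) peephole weights. The stock
no-peephole cell is available as `peephole = FALSE`; it exists both as a
modeling option and because it eases cross-checking against frameworks
whose LSTMs lack peepholes. Both modes share one code path.

The majority-vote baseline picks, per token, the label most annotators
assigned; ties are resolved by (1) any entity label beats `O` — favoring
recall — then (2) the fixed tagset order. Voting operates on the full
15-label space by default (an IOB-collapsed mode is provided), which treats
subtype disagreement as genuine disagreement.

## Tunable parameters

All defaults live in `voter_config()` and are deliberately small — the
model is meant to train on one CPU in minutes:

| parameter | default | notes |
|---|---|---|
| `char_embed_dim` / `char_hidden_dim` | 16 / 16 | character morphology is low-entropy; small dims suffice |
| `word_embed_dim` / `word_hidden_dim` | 32 / 32 | vector components per token/state |
| `attention_dim` | 16 | width of both additive scoring layers |
| `dropout` | 0.1 | drop probability, applied to word representations before the word Bi-LSTM only (the single regularization site) |
| `learning_rate` | 0.003 | Adam step size |
| `batch_size` | 8 | sentences per gradient step |
| `epochs` / `patience` | 20 / 10 | early stopping on dev entity F1 (training loss when no dev set is given) |
| `grad_clip` | 5 | global L2 gradient norm clip |
| `seed` | 42 | drives initialization, shuffling and dropout; two runs with the same seed are bitwise identical |

Initialization: Glorot-uniform matrices, zero biases except a forget-gate
bias of +1, small uniform embeddings and peephole/score vectors.

`hyperparameter_search` semantics are provided by `tune_lstm_voter()`: a
*seeded random search* (sample a configuration, train, score dev F1, keep
the log). Sequential model-based search in the TPE family has no available
R implementation, and at these model sizes random search over a small
space is an adequate, fully reproducible harness; the trial log makes the
"best trial dominates the log" property testable.

## What the synthetic generator does and does not emulate

`generate_corpus()` emulates the *statistical structure the architecture
relies on*, not real patent text:

- background tokens from a fixed common-English pool;
- entity tokens from subtype-specific morphology templates (TRIVIAL:
  stem + *-ol/-ine/-ide/-ane/-ate/-one*; FAMILY: plural-like suffixes;
  SYSTEMATIC: multi-morpheme names, sometimes with a digit token;
  FORMULA: element-symbol/digit strings; ABBREVIATION: 2–4 uppercase
  letters; IDENTIFIER: registry-style prefix + digits; MULTIPLE: spans
  like "x and y"), so character features carry real signal;
- subtype frequencies defaulting to the CEMP annotation mixture (FAMILY,
  SYSTEMATIC and TRIVIAL dominate; IDENTIFIER and MULTIPLE are rare);
- an `entity_rate` (default 0.2, the fraction of tokens inside mentions)
  and sentence lengths of 6–12 content tokens, chosen once as typical of
  abstract-like text.

`simulate_annotator()` corrupts gold labels independently per token or per
mention (label flips, boundary shifts, deletions, spurious mentions).
Real stage-one taggers err *systematically and correlatedly* — they share
training data and failure modes on rare subtypes; independent corruption is
the optimistic case for any ensemble. Passing the ensemble-gain experiment
therefore shows the machinery works end to end — representation, attention
weighting, CRF training, decoding — under the conditions the architecture
assumes, not that the same margin would appear on real corpora. Likewise
the generator's closed vocabulary makes memorization easy by design; the
memorization check is a training-dynamics sanity test, not a claim of
generalization.

## Numerical choices

- **CRF in log space.** Forward recursion and likelihoods use logsumexp
  throughout. START/STOP are two extra states whose forbidden moves carry
  −10⁴ rather than −∞, keeping all arithmetic finite (a path through a
  forbidden edge is suppressed by a factor ≈ e^−10000, far below double
  precision); the sentinel entries are reset after every optimizer step.
  Forward/partition results agree with brute-force path enumeration to
  1e−8 (tested at n ≤ 5, L ≤ 6 over 100 random instances; observed
  agreement is at machine precision).
- **Viterbi ties** go to the lowest label index at the earliest decision,
  so an all-constant score matrix decodes to the first label repeated.
  Deterministic and documented rather than meaningful.
- **IOB repair.** Model output can be malformed; the decoder applies
  conlleval-style leniency (orphan `I-s` opens a mention; a subtype change
  inside a run starts a new mention) instead of erroring.
- **Gradients.** The backward pass (peephole LSTM BPTT, both attention
  mechanisms, CRF marginals) is hand-derived in C++ and tested against
  central finite differences with a mixed absolute/relative band
  (1e−5 + 1e−4·|g|), the right comparison given O(ε) differencing noise.
  The pure-R kernels define the forward semantics; the C++ engine must
  match them to 1e−10 on random models.
- **Degenerate inputs.** Empty sequences are errors for the kernels;
  empty sentences are skipped by the encoder; an empty training set is an
  error; K = 0 simply omits the stage-one branch.
- **Determinism.** All randomness (initialization, shuffling, dropout)
  draws from R's RNG, including inside C++, so a seed pins the entire
  trajectory; predictions are RNG-free.

## Design choices that were genuinely open

- **Offsets** are 0-based half-open everywhere (TSV, annotation tables,
  in-memory), matching the dominant convention of BioCreative offset files
  and avoiding ±1 ambiguity.
- **Splitting is by document**, seed-shuffled; 60/20/20 gives dev and test
  ⌊0.2m⌋ documents each with the remainder to train, and the two-series
  scheme halves the corpus first (stage one trains on series 1, the voter
  on series 2, so the voter never sees stage-one training data).
- **Char attention is query-free** by default (scores depend only on the
  char states); using the word embedding as query is a possible extension.
- **Stage-one attention granularity**: weights are computed per component
  of the K·15 vector and aggregated per annotator for reporting — finer
  than a per-annotator softmax, and it lets the model distrust an
  annotator selectively by label.
- **Optimizer**: Adam with the standard moment constants; batching is by
  sentence count.
- The fitting surface is the classic R idiom (`lstm_voter()` + S3
  methods); `coef`/`residuals`/`simulate` methods are deliberately absent
  because a CRF tagger has no meaningful notion of them.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
the ensemble experiment uses 200 documents × 10 sentences (≈ 2,000
sentences, ≈ 1,600 train / 400 held-out), K = 3 annotators at 15/20/25%
label-flip corruption, 12 training epochs; the memorization check uses 10
sentences and up to 200 epochs; kernel oracles run at n ≤ 5 tokens and
L ≤ 6 labels where enumeration is exact. These sizes were chosen so the
whole battery runs on a single CPU in a few minutes while keeping every
comparison statistically comfortable (≈ 700 mentions in the held-out set).

## Known limitations

- Simulated annotators err independently; correlated-error simulation is
  the natural next step and would stress the ensemble far harder.
- No mini-batch padding/vectorization across sentences: training is
  sentence-sequential (fine at these sizes, not GPU-shaped).
- Sentence splitting of raw text is a trivial terminator rule; TSV input
  is assumed pre-sentenced.
- Strict-span evaluation only; no overlap credit.
- The CRF is first-order with a single transition matrix; no label
  features beyond emissions + transitions.
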