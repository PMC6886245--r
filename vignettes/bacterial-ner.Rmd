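---
title: "Recognising bacterial names with a BiLSTM-CRF and domain features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising bacterial names with a BiLSTM-CRF and domain features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacner)
```

## The task and the model

Bacterial names are hard for generic named-entity recognisers: they are
multi-token Latin binomials ("*Actinobacillus actinomycetemcomitans*"),
inconsistently capitalized and abbreviated in running text, and new strains
appear faster than curated dictionaries track them. `bacner` tags each token
of a pre-tokenized sentence with IOB2 labels (`B-bacteria`, `I-bacteria`,
`O`) using a hybrid of learned representations and two explicit domain
features.

Per token, four channels are concatenated into a 360-dim input (defaults):

| channel | default dim | what it contributes |
|---|---|---|
| word embedding | 300 | distributional semantics of the (case-folded) surface |
| char-CNN | 30 | prefix/suffix morphology (`-bacillus`, `-coccus`, epithet endings) |
| POS embedding | 25 | syntactic category (Penn tags; proper nouns are informative) |
| dict embedding | 5 | gazetteer membership computed by maximum matching |

The character channel embeds each character (25-dim), slides a width-3
convolution (30 kernels) over the same-padded sequence, applies `relu`, and
max-pools over positions. Same-padding uses a dedicated `<pad>` character
whose embedding is fixed at zero, so a one-character word still yields one
full window; an all-pad window contributes `relu(b1)`, which is zero at the
zero-bias initialization.

A bidirectional LSTM (gate equations in `lstm_step()`; 100 units per
direction by default) encodes the sequence. Zero initial states are used in
both directions and the per-position states are concatenated, so position
`t` sees the full left context in its first half and the full right context
in its second half — a property the tests check by perturbation.

The decoder is a linear-chain CRF. The transition matrix is
`(m+2) x (m+2)` with explicit start/end states; a path score adds the
emission scores of the chosen tags and every transition including
`start -> y_1` and `y_n -> end`. Transitions *into* start and *out of* end
are structurally impossible; they carry a fixed score of `-1e4` and receive
no gradient, while the start row and end column are learned like any other
parameter. The partition function is computed by the log-space forward
recursion — mathematically identical to the softmax over all `m^n` paths,
which the tests verify by literal enumeration on small instances — and
decoding is Viterbi with lowest-index tie-breaking.

## Dictionary features: bidirectional maximum matching

The gazetteer feature is computed by greedy longest-first matching of the
token sequence against a lexicon, scanned in both directions:

* forward: at each position take the longest lexicon entry starting there
  (bounded by the lexicon's maximum entry length), jump past a match;
* backward: mirror image, longest entry *ending* at the cursor.

When the two directions disagree, the published descriptions of the
algorithm leave the tie rule open, so the package fixes one and documents
it: the direction covering **more tokens** wins; on a coverage tie the
direction with **fewer matches** (longer average match) wins; a final tie
keeps the backward result — the conventional preference in maximum-matching
segmenters. Matching is case-insensitive after NFC normalization and
respects token boundaries exactly; both choices are deliberate (bacterial
capitalization is inconsistent; sub-token matches would hit inside longer
words) and the case-folding lives in one helper should a user need to
change it. Both directions are verified against an independently coded
brute-force greedy simulation on hundreds of random sentence/lexicon pairs.

The lexicon container is a hashed set of folded, space-joined token
sequences plus the maximum entry length — maximum matching only ever probes
contiguous windows up to that length, so this gives the same lookups a
token trie would, in O(1) per probe.

## Training procedure

* **Loss.** CRF negative log-likelihood of the gold path, averaged over the
  sentences of a mini-batch (default 16). Sentences are processed
  individually inside a batch and gradients accumulated, so no padding
  enters the loss, the partition function or Viterbi; the batched loss
  equals the sum of per-sentence losses by construction and is asserted
  numerically.
* **Optimizer.** Adam, learning rate 0.001. The configured decay of 0.9 is
  applied as a per-epoch multiplicative learning-rate schedule
  (`lr <- 0.9 * lr`); Adam's own moment coefficients stay at their
  conventional defaults (0.9 / 0.999). A decay-as-schedule reading was
  chosen over re-interpreting Adam's beta1 because a schedule composes with
  any optimizer and is the common usage; it can be disabled with
  `decay = 1`.
* **Dropout** (rate 0.5) is applied in two places: on the concatenated
  embedding vector entering the encoder, and on the BiLSTM output entering
  the emission projection — i.e. bracketing the encoding layer, which is
  where dropout demonstrably prevents co-adaptation in this architecture.
  Inverted scaling keeps inference dropout-free; `dropout = 0` in training
  mode reproduces inference exactly (tested).
* **Gradient clipping** at global norm 5 — standard stabilisation for
  recurrent nets; configurable off (`clip = Inf`).
* **Early stopping** on validation span-F1 with patience 5 and an absolute
  improvement tolerance of 1e-4: training stops once the last 5 evaluations
  all failed to beat the best score by more than the tolerance, and the
  returned model carries the parameters of the best epoch, not the last.
* **Initialization.** Embedding tables uniform in
  `[-sqrt(3/dim), sqrt(3/dim)]`; convolution, LSTM and projection weights
  Glorot-uniform; all biases zero; CRF transitions zero. Out-of-vocabulary
  words map to a trainable `<unk>` row; word embeddings are fine-tuned by
  default (`freeze_word_emb` turns that off when pre-trained vectors are
  supplied).
* **Determinism.** One RNG stream, seeded from `config$seed`, drives
  initialization, shuffling and dropout; a full training run is
  bit-reproducible single-threaded.

All computation is in double precision — R's native numeric — which is also
what makes the finite-difference gradient checks meaningful at relative
error 1e-4.

Gradients are hand-derived: forward–backward marginals for the CRF
(`dP = posterior - onehot(gold)`, `dT = expected - observed transition
counts`), standard backpropagation-through-time for the two LSTMs (with the
per-step pre-activation gradients pooled into a single matrix product per
mini-batch), max-pool routing plus a relu mask for the char-CNN, and sparse
row-scatter for the embedding tables. The test suite checks every parameter
family of the assembled network against central finite differences.

## The synthetic corpus generator

Training data for bacterial NER cannot be shipped here, so the generator
produces corpora with the statistical structure the model assumes, and it
is first-class tested code:

* **Entities** are pseudo-Latin binomials: a capitalized genus assembled
  from morpheme chains (`Porphyro`+`monas`) and a lowercase epithet
  (`gingiv`+`alis`). By default all lexicon entries are 2-token binomials;
  1- and 3-token fractions are configurable to exercise boundary cases.
* **Context** is a fixed 57-item filler vocabulary with Penn POS templates
  (determiners, clinical nouns, verbs, prepositions, punctuation), so the
  POS column exists without an external tagger.
* **Controlled difficulty**: each mention is out-of-lexicon with
  probability `oov_entity_rate` (a novel binomial, rejected against the
  lexicon), and abbreviated (`P. gingivalis`) with probability
  `abbrev_rate` (default 0.1, roughly the rate at which abstracts
  abbreviate after first mention). The dictionary column is produced by
  actually running the BDMM tagger against the emitted lexicon, so
  in-lexicon mentions carry their gold pattern, OOV and abbreviated ones
  read `O`, and the featurization path is exercised end to end by
  construction.
* **Determinism**: `(config, seed)` yields byte-identical corpus files.

Default shape parameters — 20 genera x 4 species, sentences of 8–18 tokens
with 1–3 mentions — mirror the density of species-rich abstract sentences.

What the generator does **not** emulate: real distributional semantics of
the context (fillers are drawn i.i.d.), discontinuous or nested mentions,
strain designations with numerals, and genuine PubMed tokenization noise.
A model that recovers held-out synthetic mentions (the end-to-end check
demands span-F1 >= 90% with 30% OOV mentions; in practice it saturates
near 100%) is therefore demonstrated to have a correct learning and
decoding pipeline — not to match any published score on real corpora.
Reproducing published numbers requires the corresponding released corpus
and the full protocol script (`inst/protocols/full_protocol.R`).

## Numerical and degenerate-input choices

* Log-partition, NLL and marginals are computed in log space with the
  max-shift; the enumeration equivalence is tested to 1e-6 and path
  probabilities sum to 1 within 1e-9 on small instances.
* Invalid IOB2 (a stray `I-X`) is repaired by re-reading it as `B-X`; every
  repair is counted and surfaced, and generated corpora must need zero
  repairs.
* Empty sentences are preserved by corpus I/O but excluded from training
  and prediction; empty words yield a zero char-CNN vector.
* Zero-denominator metrics report 0 with an explicit flag.
* Viterbi ties break toward the lowest tag index, matching the enumeration
  oracle's ordering.

## Problem sizes in the checks

The verification suite uses: exhaustive CRF enumeration on 200 instances
with `n <= 6`, `m <= 4`; 20 finite-difference instances for the CRF plus a
full-network check on a 2-sentence corpus with reduced dimensions; 500
random matching problems (<= 8 tokens, <= 10 entries) against the greedy
oracle; 500 span/tag round-trips; and one end-to-end run with 1000 training
/ 200 held-out sentences and a reduced model (50-unit BiLSTM, <= 15
epochs). These sizes make every check exact or statistically tight while
keeping the whole suite runnable on a laptop in minutes.

## Known limitations

* No raw-text preprocessing: input must already be tokenized and
  sentence-split (the corpus format's job).
* One entity type is the intended use; the machinery is alphabet-generic
  but multi-type performance is untested beyond unit level.
* No abbreviation normalization or fuzzy dictionary matching — "P.
  gingivalis" is only recognisable from learned morphology/context, not
  from the gazetteer.
* Training is single-threaded CPU; the design trades speed for exactness
  and inspectability, and large-corpus training (hundreds of thousands of
  sentences) is out of scope.
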