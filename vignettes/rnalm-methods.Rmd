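---
title: "Dual-tokenization RNA language modeling: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-tokenization RNA language modeling: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rnalm` is a desk-scale implementation of an adaptive dual-tokenization
framework for masked language modeling of non-coding RNA. This vignette is
the package's own account of the science: the model and its assumptions, the
parameters that matter, what the synthetic data emulate (and do not), the
numerical choices, and the known limits. Everything quantitative stated here
is computed by the package's tests or by `scripts/acceptance.R`; nothing is
quoted from external results.

## The modeling problem

Transformer encoders for biological sequences face a tension between
resolution and length. Nucleotide-level (NUC) tokenization — one token per
base, vocabulary {A, C, G, U} — preserves full per-position information,
which structure-level tasks (contact maps, torsion angles) require, but a
quadratic-attention encoder with a fixed context window must truncate long
sequences. Byte-pair encoding (BPE) compresses recurring substrings into
multi-character tokens, shrinking token counts several-fold so much longer
molecules fit in the same budget, at the price of per-character information
and of per-nucleotide addressability.

The framework implemented here resolves the tension three ways at once:

1. **Adaptive tokenization** (`adaptive_encode()`): sequences at or below a
   length threshold (default 1024 nt, a typical context budget) are encoded
   NUC; longer ones fall back to BPE. The boundary length counts as short.
2. **Dual pretraining** (`pretrain()`): a single parameter set is optimized
   on both token streams. Every source sequence contributes one NUC-masked
   and one BPE-masked view per epoch; the combined loss is the sum of the
   two masked-LM losses. One model in memory serves both regimes.
3. **ALiBi positional encoding**: attention logits are penalized linearly in
   token distance, `A_ij = Q_i K_j' / sqrt(d) - slope * |i - j|`, instead of
   adding positional embeddings. Because the penalty is a formula in |i - j|
   rather than a learned table, the encoder runs at any length, including
   lengths far beyond those seen in training.

## Tokenization

`train_bpe()` implements greedy BPE: each iteration counts adjacent token
pairs over the whole corpus, merges every occurrence of the most frequent
pair, and repeats until the vocabulary reaches its target size or no pair
occurs at least twice (avoiding degenerate singleton merges). Decisions the
algorithm statement leaves open, fixed here once:

* **Tie-break**: equally frequent pairs are ordered lexicographically on the
  concatenated token string. This makes training deterministic and lets an
  independent brute-force oracle reproduce the merge list exactly, which the
  test suite does on every run.
* **Counting**: pair occurrences are counted left-to-right without overlap
  within a sequence, so `"AAA"` contains one `"AA"` — matching standard BPE
  trainers and matching what the greedy replacement step can actually merge.
* **Boundaries**: merges never span records, special tokens, or the
  ambiguity symbol `N` (retained as a fifth character that NUC tokenization
  maps to `[UNK]`).
* **One vocabulary**: both schemes share a single vocabulary — five special
  tokens (`[PAD]`, `[MASK]`, `[CLS]`, `[SEP]`, `[UNK]`) in reserved low
  identifiers, the four bases, then merge tokens (default total 4096). A
  single embedding table is the minimal consistent reading of one model
  trained on two streams; NUC simply uses the base subset.

All ingest goes through `normalize_sequence()`: uppercase, T→U (DNA input is
unified to RNA), and a stated policy for foreign characters (reject, replace
with `N`, or drop). Published base-composition tables for large RNA
collections are printed with T; internally everything is RNA.

## The encoder

`init_encoder()` builds a pre-layer-norm bidirectional Transformer with GELU
feed-forward blocks, learned token embeddings tied to the output projection,
and no positional signal other than ALiBi. The per-head slopes follow the
geometric progression 1/2, 1/4, ..., 1/256 at 8 heads; for n heads the
package uses `slope_h = 2^(-8h/n)`, which reproduces those values at n = 8.
Small slopes preserve long-range heads; large slopes make local heads.

The numerical core — forward pass and analytic backpropagation — is written
in RcppArmadillo (`src/encoder.cpp`). The backward pass is verified against
central finite differences in development and against a full matrix-algebra
oracle of the forward pass in the test suite. The compact implementation is
dropout-free: all evaluation operations are deterministic given parameters,
and the desk-scale training runs are small enough that regularization by
dropout was judged unnecessary; the configuration field is retained and a
nonzero value is rejected rather than silently ignored.

Default desk-scale configuration: 2 layers, 4 heads, hidden width 64,
feed-forward 256. The architecture is expressible at publication scale
(hundreds of millions of parameters) through `model_config()`, but nothing
in this package attempts to reach it.

## Pretraining objective and loop

`masking_policy()` supports the two standard protocols: random masking of a
fixed fraction (default 15%, minimum one position) and central-token masking
(position floor(n/2), 0-based). Selected tokens are replaced by `[MASK]`
("pure-mask", the default, as the formal statement of the objective says
"replaced with a mask token"); the BERT-style 80/10/10 replacement is
available by configuration. Special tokens are never masked.

The loss is accumulated in log base 2, so that perplexity is exactly
`2^loss` and a forced-uniform model scores exactly `log2 |V|` bits per
masked token — both facts are asserted by tests. The training loop is Adam
with linear warmup over 6% of steps and linear decay to 2% of the peak rate
(the full-scale defaults of `train_config()`), global gradient-norm
clipping (default 1.0; the desk-scale demonstrations use 5.0 with a peak
rate of 3e-3, chosen once for the small-batch regime), and strict
alternation of NUC and BPE optimizer steps. The alternation rule is a
design choice the objective statement leaves open; it guarantees both
streams see the same optimizer state trajectory.

## Evaluation

`masked_lm_eval()` reports, per sequence and pooled: the average negative
log2 probability at masked sites, its power of two (perplexity), and
recovery accuracy (argmax correctness). As printed, the loss formula in the
source analysis lacks the negation and averaging that its own prose and the
perplexity definition require; the implementation uses the average negative
log-probability so that perplexity ≥ 1 always holds. `restrict_vocab`
renormalizes and takes the argmax over the scheme's sub-vocabulary, moving
chance accuracy from ~1/|V| to ~1/4 for NUC — the chance-level argument for
why BPE recovery numbers are not comparable to NUC ones. `encoder = NULL`
evaluates the forced-uniform baseline exactly.

`silhouette_eval()` implements the silhouette coefficient
`s(i) = (b(i) - a(i)) / max(a(i), b(i))` directly, with the singleton
convention `s = 0` and a choice of euclidean or cosine distance. It is
cross-checked against a brute-force oracle and against the independent
`cluster` package implementation. `cluster_eval()` embeds sequences
(adaptive tokenization, mean or CLS pooling) and scores label separation on
the raw embeddings by default. When a 2-D reduction is requested it uses
classical multidimensional scaling of the chosen distance matrix — a
deterministic reduction preferred here over stochastic neighbor embeddings
because no t-SNE implementation is among the package's dependencies and
determinism simplifies the reproducibility contract; silhouettes are
reported for both spaces, since low-dimensional projections can change them
substantially.

## Information-theoretic analysis

`build_entropy_report()` reproduces the tokenization analysis end to end:
character frequencies → nucleotide entropy `H = -Σ p log2 p`; BPE token
counts → rank-frequency distribution (1-based ranks, lexicographic ties) →
a least-squares fit of `log2 p_i = log2 C - a·i`, the exponential decay law
`P(x_i) = C/2^(a i)`; empirical token entropy; the closed-form entropy
`log2((C+1)^((C+1)/C) / C)` evaluated at the fitted C; the observed mean
token length; and the per-character ratio.

Two recorded subtleties:

* Published 4-decimal frequency tables can sum to 0.9999; frequencies within
  0.001 of 1 are renormalized on ingest and the deviation recorded.
* Evaluating the closed form at the published fit scale C ≈ 0.005086 gives
  ≈ 9.066 bits, while the downstream per-character arithmetic in the source
  analysis proceeds from ≈ 9.104 bits. Both the empirical and the
  closed-form token entropies are therefore always reported side by side;
  ratio computations default to the empirical value, and nothing asserts
  equality between the closed form and any particular constant.

## Synthetic data: what it emulates, and what it does not

No external corpus is downloaded; `generate_corpus()` and
`generate_task_fixture()` produce everything the tests and the acceptance
script consume. The generators emulate four features of real data:

* **Composition**: background nucleotides are i.i.d. draws from the observed
  large-corpus frequencies (A 0.2726, C 0.2664, G 0.2465, U 0.2144,
  renormalized).
* **Length structure**: fixed, uniform, or geometric-tail (exponential-type
  right tail, capped at a configurable maximum, default 10,000 nt) length
  models.
* **Token statistics**: motif-structured corpora induce skewed,
  approximately exponentially decaying token rank-frequency distributions
  once a BPE model is trained on them.
* **Learnable planted signal**: every downstream fixture's labels are a
  known function of its sequences, so a Bayes-optimal reference rule exists
  and trainability is a testable property rather than a hope.

The canonical pretraining corpus (`pretrain_corpus_spec()`) tiles each
120-nt sequence from four fixed 12-nt motifs separated by 0–2 background
nucleotides. This makes the masked-LM signal local and strong — inside a
motif the masked base is determined by its unmasked neighbors — which is
what lets a 2-layer model demonstrably exceed the 0.25 chance recovery floor
within minutes of CPU time. Insert-mode corpora (isolated motifs in long
random background) carry a weaker, longer-range signal that the same model
learns much more slowly; both modes are available.

Task fixtures mirror the shapes of real downstream datasets (pair
interaction of a short and a long RNA; fixed-width classification windows;
symmetric zero-diagonal pairing maps from well-nested hairpins with
complementary bases forced at paired positions; distance maps from a
deterministic 3-D helical walk over those structures; seven torsion angles
per position as fixed functions of the local dinucleotide plus bounded
noise). They are stand-ins: they mimic shapes and learnability, not
biology. A passing head test shows the head extracts planted signal from
frozen embeddings better than a trivial baseline; it says nothing about
accuracy on real RNA structure.

## Downstream heads

All heads read a frozen backbone; freezing is asserted bit-for-bit in
tests. The sequence-level heads (pair interaction, classification) consume
concatenated mean-pooled embeddings through a small dense classifier
trained with Adam. `pairwise_feature_map()` provides the plain
concatenation featurization for per-cell work.

The map heads needed a design iteration worth recording. A contact between
positions i and j is a *bilinear* relation between the two embeddings —
"base at i complementary to base at j" is a sum of products of linear
readouts, exactly the XOR situation in which a function has no linear
correlation with its inputs. A conv head fed only concatenated embeddings
therefore starts on a gradient plateau: in development it failed to move
off the all-negative solution at this data scale regardless of width,
learning rate, or epochs, while a hand-written complementarity-run rule
scored F1 ≈ 0.6 on the same fixtures. The shipped head makes the bilinear
structure explicit: embeddings are passed through a fixed seeded 24-dim
projection, outer products of the two projected vectors form the feature
channels, taken at the kernel taps along the anti-diagonal (the direction
in which stems stack), and a single linear convolution kernel over those
channels yields the per-cell logit, symmetrized by averaging with its
transpose. Because the model is linear, the fit is convex and is done with
a ridge-penalized weighted logistic regression (glmnet; fixed small
penalty, positive-class reweighting) on the upper triangle only — the
matrix is symmetric. Gradient training of the same convex objective proved
seed-fragile; the GLM fit is deterministic and uniformly beat it in
robustness. The distance head shares the featurization with an identity
link, ridge-penalized least squares, and zero-clamped predictions. The
torsion head is a per-position dense layer producing 14 sine/cosine
outputs trained with mean squared error; mean absolute error in degrees,
with circular wrap `min(|Δ|, 360 - |Δ|)`, is an evaluation-only quantity.
F1 over unordered pairs uses the convention that a perfect-empty
prediction scores 1 (otherwise the metric is undefined on unpaired
sequences) and zero denominators otherwise score 0.

## Numerical choices and degenerate inputs

* Log base 2 throughout; natural-log intermediates are converted exactly.
* Layer-norm epsilon 1e-5; attention softmax is max-shifted.
* Probability rows from `forward_mlm()` sum to 1 within 1e-9 and are tested.
* Empty corpora, single-cluster silhouettes, all-special pooling requests,
  zero-capacity vocabularies, constant-truth R², and sin = cos = 0 angle
  decoding all raise informative errors rather than returning numbers.
* Rank index for decay fits is 1-based and recorded in the fit object.

## Problem sizes used in the packaged demonstrations

The tests and the acceptance script run, on one CPU in minutes: BPE
vocabularies of 64–256 over corpora of a few hundred sequences; dual
pretraining of the 2-layer/width-64 encoder on 5,000 tiled 120-nt sequences
for 2 epochs at batch size 24 (the package's chosen desk-scale
demonstration of the dual objective); and head training on fixtures of
24–80 nt. These sizes are the package's own study conditions, selected so
that every claim is verifiable on modest hardware.

## Known limitations

* Desk scale only: nothing here reproduces published benchmark scores of
  full-scale RNA language models; those require released weights and
  external datasets, both out of scope by design.
* The BPE trainer recounts pairs from scratch each iteration (exactly
  oracle-equivalent, O(merges × corpus)); it is meant for corpora up to a
  few megabases, not for training production tokenizers.
* The encoder has no dropout and no mixed precision, and trains on one
  device.
* Geometric-tail lengths approximate heavy-tailed natural length
  distributions only to first order.
* The torsion and distance fixtures are geometric toys; their "angles" and
  "distances" are internally consistent but not physical.
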