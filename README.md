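# rnalm — dual-tokenization RNA language modeling with linear attention biases

`rnalm` is a desk-scale R implementation of an adaptive dual-tokenization
framework for masked language modeling (MLM) of non-coding RNA. It is aimed
at computational biologists and methods researchers who want to study — on
ordinary hardware, with fully synthetic, seeded data — how tokenization
granularity, attention biasing, and masked-LM pretraining interact for RNA
sequence models.

## The method in brief

An RNA sequence **r** = (r₁, …, rₙ) is tokenized two ways:

* **NUC**: one token per nucleotide, vocabulary {A, C, G, U} — full
  per-position fidelity, needed by structure-level tasks;
* **BPE**: byte-pair encoding, which greedily merges the most frequent
  adjacent token pair until a target vocabulary size is reached, compressing
  recurring substrings so long molecules fit a fixed token budget.

A single bidirectional Transformer encoder handles both streams. Attention
uses **ALiBi** distance penalties instead of positional embeddings:

    A_ij = Q_i K_j' / sqrt(d)  −  α_h · |i − j|,      α_h = 2^(−8h/H)

which lets the encoder run at lengths far beyond those seen in training.
Pretraining minimizes the summed dual masked-LM objective

    L_total = − Σ_{i∈M_BPE} log₂ p(β_i | r_BPE^mask) − Σ_{i∈M_NUC} log₂ p(ν_i | r_NUC^mask)

over one parameter set Θ. At inference, **adaptive tokenization** dispatches
by length: sequences ≤ 1024 nt are encoded NUC, longer ones BPE.

The package also implements the surrounding analysis suite: masked-LM
perplexity (2^loss) and token-recovery accuracy under central or random-15%
masking; silhouette-based clustering evaluation of pooled embeddings; an
information-theoretic account of tokenization (character entropy, the
exponential rank-frequency law P(xᵢ) = C/2^(a·i), closed-form and empirical
token entropy, per-character entropy ratios); and frozen-backbone
fine-tuning heads for pair interaction, secondary-structure contact maps,
distance maps, and backbone torsion angles. Seeded generators provide
corpora and task fixtures with known planted signal, so everything is
testable without downloading any external dataset.

## Worked example

```r
library(rnalm)

# 1. a seeded synthetic corpus with planted motif structure
corpus <- generate_corpus(pretrain_corpus_spec(5000, seed = 1))

# 2. train a BPE tokenizer and inspect the compression
bpe <- train_bpe(corpus[1:1000], target_vocab_size = 128)
mean_token_length(bpe, corpus[1:100])
#> [1] 10.84991

# 3. dual masked-LM pretraining of a compact ALiBi encoder (~3 min, 1 CPU)
fit <- pretrain(corpus, bpe,
                model_config(vocab_size = length(bpe$vocab), seed = 1),
                train_config(lr = 3e-3, batch_size = 24, epochs = 2,
                             seed = 1, grad_clip = 5))
nuc <- fit$log[fit$log$scheme == "NUC", ]
tapply(nuc$loss_bits, nuc$epoch, mean)   # NUC loss, bits per masked token
#>        1        2
#> 2.346100 1.843065

# 4. held-out recovery accuracy under 15% masking, NUC vocabulary (chance 0.25)
held <- generate_corpus(pretrain_corpus_spec(200, seed = 999))
masked_lm_eval(fit$encoder, held, scheme = "NUC", protocol = "random",
               restrict_vocab = TRUE, bpe_model = bpe, seed = 1)
#> masked-LM eval (NUC, random, restricted vocab): perplexity 3.3673, accuracy 0.4528 over 3600 masked tokens

# 5. the information-theoretic analysis of the published frequency table
char_entropy(c(A = 0.2726, T = 0.2144, C = 0.2664, G = 0.2465))
#> [1] 1.993929
per_char_ratio(9.1044, 6.0768, 1.9939)
#> $per_char  1.498223
#> $ratio     0.7514032
```

The recovery accuracy of 0.45 against a 0.25 chance floor shows the tiny
encoder has learned the planted motif structure from context alone; the
entropy ratio ≈ 0.75 quantifies the per-character information given up by
BPE compression in exchange for ~6× longer context at full scale.

A command-line entry point wraps the same functionality
(`inst/cli/rnalm`): `gen-data`, `train-tokenizer`, `tokenize`, `pretrain`,
`eval-mlm`, `cluster-eval`, `analyze-entropy`, `finetune`.

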