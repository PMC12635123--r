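# Shared small fixtures built once per test run.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# a small BPE model trained on a motif-planted corpus
tiny_bpe <- function() {
  cached("tiny_bpe", {
    spec <- corpus_spec(300, length_model = length_fixed(80),
                        motif_set = default_motif_set(), seed = 11)
    train_bpe(generate_corpus(spec), 64)
  })
}

# a briefly pretrained tiny backbone (motif corpus), reused by head tests
tiny_backbone <- function() {
  cached("tiny_backbone", {
    spec <- corpus_spec(400, length_model = length_fixed(60),
                        motif_set = default_motif_set(), seed = 21)
    corpus <- generate_corpus(spec)
    bpe <- tiny_bpe()
    mc <- model_config(n_layers = 2, n_heads = 4, d = 32, d_ff = 64,
                       vocab_size = length(bpe$vocab), seed = 21)
    tc <- train_config(lr = 2e-3, batch_size = 32, epochs = 2, seed = 21)
    pretrain(corpus, bpe, mc, tc)$encoder
  })
}
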