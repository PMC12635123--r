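test_that("random masking selects the stated number of non-special positions", {
  v <- new_vocabulary()
  ids <- vocab_id(v, sample(c("A", "C", "G", "U"), 100, replace = TRUE))
  ts <- structure(list(scheme = "NUC", ids = ids, source_length = 100L),
                  class = "token_seq")
  m <- mask_tokens(ts, masking_policy("random", 0.15, seed = 3), v)
  expect_length(m$positions, 15)
  expect_true(all(m$ids_masked[m$positions] == 2L))
  expect_identical(m$targets, ids[m$positions])
  # unmasked positions untouched
  expect_identical(m$ids_masked[-m$positions], ids[-m$positions])
  # rate 0 -> identity
  m0 <- mask_tokens(ts, masking_policy("random", 0), v)
  expect_length(m0$positions, 0)
  expect_identical(m0$ids_masked, ids)
  # minimum one mask when the rate is positive
  short <- structure(list(scheme = "NUC", ids = ids[1:3], source_length = 3L),
                     class = "token_seq")
  expect_length(mask_tokens(short, masking_policy("random", 0.15, seed = 1), v)$positions, 1)
})

test_that("central masking hits position floor(n/2), 0-based", {
  v <- new_vocabulary()
  ids <- vocab_id(v, sample(c("A", "C", "G", "U"), 41, replace = TRUE))
  ts <- structure(list(scheme = "NUC", ids = ids, source_length = 41L),
                  class = "token_seq")
  m <- mask_tokens(ts, masking_policy("central"), v)
  expect_equal(m$positions, 21) # 0-based index 20
})

test_that("specials are never masked and masking is seed-deterministic", {
  v <- new_vocabulary()
  ids <- c(3L, vocab_id(v, strsplit("ACGUACGUACGUACGUACGU", "")[[1]]), 4L)
  ts <- structure(list(scheme = "NUC", ids = ids, source_length = 20L),
                  class = "token_seq")
  pol <- masking_policy("random", 0.5, seed = 11)
  m1 <- mask_tokens(ts, pol, v)
  m2 <- mask_tokens(ts, pol, v)
  expect_identical(m1, m2)
  expect_false(1L %in% m1$positions)
  expect_false(length(ids) %in% m1$positions)
})

test_that("dual batches pair every sequence's NUC and BPE views per epoch", {
  bpe <- tiny_bpe()
  corpus <- generate_corpus(corpus_spec(10, length_model = length_fixed(40),
                                        seed = 2))
  b <- dual_batch_iterator(corpus, bpe, masking_policy("random", 0.15),
                           batch_size = 4, epochs = 1, seed = 5)
  n_nuc <- sum(vapply(b, function(x) length(x$nuc$seqs), numeric(1)))
  n_bpe <- sum(vapply(b, function(x) length(x$bpe$seqs), numeric(1)))
  expect_equal(n_nuc, 10)
  expect_equal(n_bpe, 10)
  # same seed -> identical order
  b2 <- dual_batch_iterator(corpus, bpe, masking_policy("random", 0.15),
                            batch_size = 4, epochs = 1, seed = 5)
  expect_identical(lapply(b, `[[`, "indices"), lapply(b2, `[[`, "indices"))
  # NUC view has one token per nucleotide; BPE never more
  expect_equal(lengths(b[[1]]$nuc$seqs),
               setNames(nchar(corpus[b[[1]]$indices]), NULL),
               ignore_attr = TRUE)
  expect_true(all(lengths(b[[1]]$bpe$seqs) <= lengths(b[[1]]$nuc$seqs)))
})

test_that("the dual loss is additive over streams and exactly chance for uniform output", {
  bpe <- tiny_bpe()
  v <- bpe$vocab
  cfg <- model_config(n_layers = 1, n_heads = 1, d = 8, d_ff = 16,
                      vocab_size = length(v), seed = 1)
  enc <- init_encoder(cfg, v)
  corpus <- generate_corpus(corpus_spec(6, length_model = length_fixed(30),
                                        seed = 3))
  b <- dual_batch_iterator(corpus, bpe, masking_policy("random", 0.2),
                           batch_size = 6, epochs = 1, seed = 1)[[1]]
  total <- dual_mlm_loss(enc, b$nuc, b$bpe)
  l_nuc <- rnalm:::stream_loss(enc, b$nuc)$loss_bits
  l_bpe <- rnalm:::stream_loss(enc, b$bpe)$loss_bits
  expect_equal(total, l_nuc + l_bpe)
  expect_gte(total, 0)

  # forced-uniform model: zero embeddings and output bias -> logits constant,
  # per-token loss is exactly log2 |V|
  encu <- enc
  encu$params$emb[] <- 0
  encu$params$out_b[] <- 0
  res <- rnalm:::stream_loss(encu, b$nuc)
  expect_equal(res$loss_bits / res$n_masked, log2(length(v)), tolerance = 1e-12)
})

test_that("the LR schedule warms up linearly then decays to the final fraction", {
  tc <- train_config(lr = 1e-3, warmup_ratio = 0.1, final_lr_frac = 0.02,
                     batch_size = 4, epochs = 1)
  total <- 100
  expect_equal(lr_at_step(0, total, tc), 0)
  expect_equal(lr_at_step(10, total, tc), 1e-3) # end of warmup
  expect_equal(lr_at_step(100, total, tc), 1e-3 * 0.02)
  mid <- lr_at_step(55, total, tc)
  expect_lt(mid, 1e-3)
  expect_gt(mid, 1e-3 * 0.02)
})

test_that("a tiny dual pretraining run reduces the loss and checkpoints reload", {
  spec <- corpus_spec(120, length_model = length_fixed(60),
                      motif_set = default_motif_set(), seed = 33)
  corpus <- generate_corpus(spec)
  bpe <- tiny_bpe()
  mc <- model_config(n_layers = 2, n_heads = 4, d = 32, d_ff = 64,
                     vocab_size = length(bpe$vocab), seed = 33)
  tc <- train_config(lr = 2e-3, batch_size = 24, epochs = 3, seed = 33)
  dir <- withr::local_tempdir()
  fit <- pretrain(corpus, bpe, mc, tc, checkpoint_dir = dir)
  em <- tapply(fit$log$loss_bits, fit$log$epoch, mean)
  expect_lt(em[length(em)], em[1])
  expect_true(all(is.finite(fit$log$loss_bits)))
  # reloaded checkpoint reproduces the loss on a probe batch
  back <- load_encoder(file.path(dir, "encoder_final.rds"))
  b <- dual_batch_iterator(corpus[1:8], bpe, masking_policy("random", 0.15),
                           batch_size = 8, epochs = 1, seed = 2)[[1]]
  expect_identical(dual_mlm_loss(back, b$nuc, b$bpe),
                   dual_mlm_loss(fit$encoder, b$nuc, b$bpe))
  # one parameter set serves both streams: the training log interleaves them
  expect_setequal(unique(fit$log$scheme), c("NUC", "BPE"))
  expect_true(all(fit$log$scheme[seq(1, nrow(fit$log), 2)] == "NUC"))
  expect_true(all(fit$log$scheme[seq(2, nrow(fit$log), 2)] == "BPE"))
})
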