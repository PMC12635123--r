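test_that("uniform predictor perplexity equals the effective vocabulary size", {
  bpe <- tiny_bpe()
  seqs <- generate_corpus(corpus_spec(10, length_model = length_fixed(60),
                                      seed = 4))
  # restricted NUC vocabulary of 4 -> perplexity exactly 4, chance accuracy 1/4
  r4 <- masked_lm_eval(NULL, seqs, scheme = "NUC", restrict_vocab = TRUE,
                       bpe_model = bpe, seed = 1)
  expect_equal(r4$perplexity, 4)
  expect_equal(r4$accuracy, 0.25)
  # unrestricted -> perplexity equals the full vocabulary size
  rV <- masked_lm_eval(NULL, seqs, scheme = "NUC", restrict_vocab = FALSE,
                       bpe_model = bpe, seed = 1)
  expect_equal(rV$perplexity, length(bpe$vocab))
  expect_equal(rV$accuracy, 1 / length(bpe$vocab))
})

test_that("perplexity is exactly 2 to the mean masked loss", {
  bpe <- tiny_bpe()
  enc <- init_encoder(model_config(n_layers = 1, n_heads = 2, d = 8, d_ff = 16,
                                   vocab_size = length(bpe$vocab), seed = 6),
                      bpe$vocab)
  seqs <- generate_corpus(corpus_spec(8, length_model = length_fixed(50),
                                      seed = 9))
  for (protocol in c("random", "central")) {
    rep <- masked_lm_eval(enc, seqs, scheme = "NUC", protocol = protocol,
                          bpe_model = bpe, seed = 2)
    expect_equal(rep$per_sequence$perplexity,
                 2^rep$per_sequence$loss_bits)
    expect_equal(rep$perplexity, 2^rep$mean_loss_bits)
    expect_true(all(rep$per_sequence$perplexity >= 1))
    expect_true(all(rep$per_sequence$accuracy >= 0 &
                      rep$per_sequence$accuracy <= 1))
    if (protocol == "central")
      expect_true(all(rep$per_sequence$n_masked == 1))
  }
})

test_that("a half-probability predictor scores perplexity 2", {
  # direct arithmetic on the definition: p(true) = 0.5 at every masked site
  loss <- mean(-log2(rep(0.5, 10)))
  expect_identical(2^loss, 2)
})

test_that("silhouette matches the brute-force oracle on random instances", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    k <- sample(2:5, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    labels <- sample(rep_len(seq_len(k), n))
    got <- silhouette_eval(pts, labels)
    expect_equal(got$s, oracle_silhouette(pts, labels), tolerance = 1e-9)
    expect_true(all(got$s >= -1 & got$s <= 1))
    expect_equal(got$mean, mean(got$s))
  }
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  set.seed(3)
  pts <- matrix(rnorm(60), 30, 2)
  labels <- sample(1:3, 30, replace = TRUE)
  got <- silhouette_eval(pts, labels)
  ref <- cluster::silhouette(labels, dist(pts))
  expect_equal(got$s, as.numeric(ref[, "sil_width"]), tolerance = 1e-9)
})

test_that("the two-cluster hand example evaluates exactly", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  labels <- c("a", "a", "b", "b")
  rep <- silhouette_eval(pts, labels)
  expect_equal(rep$s, c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5),
               tolerance = 1e-6)
  expect_equal(rep$mean, 0.89975, tolerance = 1e-4)
})

test_that("silhouette edge conventions hold", {
  # coincident-point clusters separated by distance -> all s = 1
  pts <- rbind(matrix(0, 3, 2), matrix(5, 3, 2))
  rep <- silhouette_eval(pts, rep(c("x", "y"), each = 3))
  expect_equal(rep$s, rep(1, 6))
  # a(i) = b(i) -> s = 0 (boundary point): for the point at 0,
  # a = |0-2| = 2 and b = mean(|0-1|, |0-3|) = 2
  pts3 <- matrix(c(0, 2, 1, 3), 4, 1)
  lab3 <- c("a", "a", "b", "b")
  s_mid <- silhouette_eval(pts3, lab3)$s
  expect_equal(s_mid[1], 0) # equidistant point scores zero
  # degenerate: identical embeddings
  expect_error(silhouette_eval(matrix(1, 4, 2), c(1, 1, 2, 2)), "degenerate")
  expect_error(silhouette_eval(matrix(rnorm(8), 4, 2), rep(1, 4)),
               ">= 2 clusters")
  # singleton cluster scores zero
  s_single <- silhouette_eval(matrix(c(0, 1, 9), 3, 1), c("a", "a", "b"))
  expect_equal(s_single$s[3], 0)
})

test_that("embedding clustering separates motif families and nulls out under permutation", {
  bpe <- tiny_bpe()
  enc <- tiny_backbone()
  fam_a <- corpus_spec(25, length_model = length_fixed(60),
                       motif_set = list(list(motif = "GGACUAGCGGAU", prob = 1),
                                        list(motif = "UUCGACGGAUCC", prob = 1)),
                       seed = 51)
  fam_b <- corpus_spec(25, length_model = length_fixed(60),
                       motif_set = list(list(motif = "CCUAGGUUACGC", prob = 1),
                                        list(motif = "GCGUAAACCGUU", prob = 1)),
                       seed = 52)
  seqs <- c(generate_corpus(fam_a), generate_corpus(fam_b))
  labels <- rep(c("famA", "famB"), each = 25)
  rep <- cluster_eval(enc, seqs, labels, bpe, reduce_2d = TRUE, seed = 1)
  expect_gt(rep$mean, 0)
  expect_length(rep$reduced$s, 50)
  # permuted labels -> mean silhouette near zero across seeds
  means <- vapply(1:5, function(s) {
    perm <- with_seed_local(s, sample(labels))
    silhouette_eval(rep$embeddings, perm)$mean
  }, numeric(1))
  expect_true(all(abs(means) < 0.1))
})
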