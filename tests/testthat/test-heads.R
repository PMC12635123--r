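test_that("pairwise features concatenate the two position embeddings", {
  E <- matrix(c(1, 2), 2, 1) # d = 1, embeddings x = 1, y = 2
  fm <- pairwise_feature_map(E)
  expect_equal(dim(fm), c(2, 2, 2))
  expect_equal(fm[1, 2, ], c(1, 2))
  expect_equal(fm[2, 1, ], c(2, 1))
  # swapping i and j swaps the halves
  set.seed(2)
  E2 <- matrix(rnorm(12), 4, 3)
  fm2 <- pairwise_feature_map(E2)
  expect_equal(dim(fm2), c(4, 4, 6))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(fm2[i, j, ], c(E2[i, ], E2[j, ]))
    expect_equal(fm2[i, j, 1:3], fm2[j, i, 4:6])
  }
  expect_error(pairwise_feature_map(matrix(1, 1, 3)), "at least 2")
})

test_that("structure F1 matches a brute-force pair-set oracle", {
  set.seed(44)
  for (i in 1:25) {
    L <- sample(4:20, 1)
    truth <- matrix(0, L, L)
    pred <- matrix(0, L, L)
    for (k in seq_len(sample(0:6, 1))) {
      ij <- sort(sample(L, 2))
      truth[ij[1], ij[2]] <- truth[ij[2], ij[1]] <- 1
    }
    for (k in seq_len(sample(0:6, 1))) {
      ij <- sort(sample(L, 2))
      pred[ij[1], ij[2]] <- pred[ij[2], ij[1]] <- 1
    }
    got <- structure_f1(pred, truth)
    # oracle over unordered pairs
    tp <- fp <- fn <- 0
    for (a in 1:(L - 1)) for (b in (a + 1):L) {
      if (pred[a, b] > 0.5 && truth[a, b] > 0.5) tp <- tp + 1
      if (pred[a, b] > 0.5 && truth[a, b] <= 0.5) fp <- fp + 1
      if (pred[a, b] <= 0.5 && truth[a, b] > 0.5) fn <- fn + 1
    }
    if (tp + fp + fn == 0) {
      expect_equal(unname(got["f1"]), 1)
    } else {
      P <- if (tp + fp == 0) 0 else tp / (tp + fp)
      R <- if (tp + fn == 0) 0 else tp / (tp + fn)
      F <- if (P + R == 0) 0 else 2 * P * R / (P + R)
      expect_equal(unname(got["f1"]), F)
    }
  }
})

test_that("structure F1 hand examples and conventions", {
  L <- 8
  truth <- matrix(0, L, L)
  truth[1, 5] <- truth[5, 1] <- 1
  truth[2, 4] <- truth[4, 2] <- 1
  pred <- matrix(0, L, L)
  pred[1, 5] <- pred[5, 1] <- 1
  pred[3, 7] <- pred[7, 3] <- 1
  got <- structure_f1(pred, truth)
  expect_equal(unname(got), c(0.5, 0.5, 0.5))
  expect_equal(unname(structure_f1(truth, truth)["f1"]), 1)
  expect_equal(unname(structure_f1(matrix(0, L, L), truth)["f1"]), 0)
  expect_equal(unname(structure_f1(matrix(0, L, L), matrix(0, L, L))["f1"]), 1)
  expect_error(structure_f1(matrix(0, 3, 3), truth), "shapes differ")
})

test_that("angle encoding and decoding are inverse with circular wrap", {
  expect_equal(decode_angles(matrix(c(0, 1, rep(c(0, 1), 6)), 1))[1, 1], 0)
  expect_equal(decode_angles(matrix(c(1, 0, rep(c(0, 1), 6)), 1))[1, 1], 90)
  set.seed(5)
  ang <- matrix(runif(7 * 30, -179.9, 180), 30, 7)
  expect_equal(decode_angles(encode_angles(ang)), ang, tolerance = 1e-9)
  # sin^2 + cos^2 = 1 per encoded pair
  sc <- encode_angles(ang)
  expect_equal(sc[, seq(1, 13, 2)]^2 + sc[, seq(2, 14, 2)]^2,
               matrix(1, 30, 7), tolerance = 1e-9)
  expect_error(decode_angles(matrix(0, 1, 14)), "undefined angle")
})

test_that("circular MAE wraps at 180 degrees", {
  expect_equal(circular_mae(matrix(179), matrix(-179)), 2)
  expect_equal(circular_mae(matrix(10), matrix(-10)), 20)
  expect_equal(circular_mae(matrix(c(0, 90)), matrix(c(0, 90))), 0)
})

test_that("R-squared matches direct arithmetic", {
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  truth <- c(1, 2, 3, 4)
  expect_equal(r2_score(rep(mean(truth), 4), truth), 0)
  expect_equal(r2_score(c(1, 2, 5), c(1, 2, 3)), -1)
  expect_error(r2_score(c(1, 2), c(3, 3)), "constant truth")
})

test_that("every head beats its trivial baseline with a frozen backbone", {
  enc <- tiny_backbone()
  probe <- encoder_states(enc, encode_nuc(enc$vocab, "ACGUACGUAC"))
  params_before <- enc$params

  fx_pair <- generate_task_fixture("pair_interaction", n = 400, seed = 71,
                                   len = 30, len2 = 60)
  h_pair <- train_head(enc, fx_pair, head_config(epochs = 400, lr = 5e-3,
                                                 seed = 71))
  expect_gt(h_pair$metrics$accuracy, 0.65)
  expect_gt(h_pair$metrics$accuracy, h_pair$metrics$baseline_accuracy)

  fx_cls <- generate_task_fixture("seq_classification", n = 200, seed = 72,
                                  len = 60)
  h_cls <- train_head(enc, fx_cls, head_config(epochs = 400, lr = 5e-3,
                                               seed = 72))
  expect_gt(h_cls$metrics$accuracy, h_cls$metrics$baseline_accuracy)

  fx_ss <- generate_task_fixture("pairing_map", n = 40, seed = 73, len = 24)
  h_ss <- train_head(enc, fx_ss, head_config(seed = 73))
  expect_gt(h_ss$metrics$mean_f1, h_ss$metrics$baseline_f1)

  fx_dm <- generate_task_fixture("distance_map", n = 40, seed = 74, len = 24)
  h_dm <- train_head(enc, fx_dm, head_config(seed = 74))
  expect_gt(h_dm$metrics$r2, h_dm$metrics$baseline_r2)

  fx_ta <- generate_task_fixture("torsion_angles", n = 30, seed = 75,
                                 len = 40, noise_sd = 0)
  h_ta <- train_head(enc, fx_ta, head_config(epochs = 600, lr = 2e-3,
                                             seed = 75))
  # validation MSE decreases across training
  expect_lt(tail(h_ta$metrics$val_mse, 1), h_ta$metrics$val_mse[1])
  expect_lt(h_ta$metrics$mae_degrees, h_ta$metrics$baseline_mae_degrees)

  # frozen backbone: parameters and probe outputs bit-identical
  expect_identical(enc$params, params_before)
  expect_identical(encoder_states(enc, encode_nuc(enc$vocab, "ACGUACGUAC")),
                   probe)
})
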