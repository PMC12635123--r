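# Frozen-backbone fine-tuning heads and their metrics: sequence(-pair)
# classification, pairwise map prediction (secondary-structure contacts and
# distances), and per-nucleotide torsion angles. The backbone encoder is
# only ever read; heads are small dense/convolutional networks trained with
# Adam on features extracted once per record.

#' Head configuration
#'
#' @param hidden hidden width of the iteratively trained dense heads
#'   (pair interaction, sequence classification, torsion).
#' @param kernel receptive-field size of the single-layer convolutional map
#'   heads (odd; taps run along the anti-diagonal stem direction).
#' @param lr,epochs Adam learning rate and epoch count for the dense heads;
#'   the map heads are fit as ridge-penalized GLMs and ignore both.
#' @param holdout held-out fraction for evaluation.
#' @param seed integer seed (data order, split, initialization).
#' @param frozen backbone-frozen flag; only `TRUE` is supported -- the
#'   backbone is never updated.
#' @return a `head_config`.
#' @export
head_config <- function(hidden = 32L, kernel = 3L, lr = 1e-2,
                        epochs = 30L, holdout = 0.2, seed = 0L,
                        frozen = TRUE) {
  if (!isTRUE(frozen))
    stop_usage("only frozen-backbone training is supported")
  if (kernel %% 2L != 1L) stop_usage("kernel must be odd")
  structure(list(hidden = as.integer(hidden),
                 kernel = as.integer(kernel), lr = lr,
                 epochs = as.integer(epochs), holdout = holdout,
                 seed = as.integer(seed), frozen = TRUE),
            class = "head_config")
}

#' Pairwise feature map from per-position embeddings
#'
#' Entry `(i, j)` is the concatenation of embedding `i` and embedding `j`,
#' the featurization consumed by the pairwise convolutional heads; swapping
#' `i` and `j` swaps the two halves.
#'
#' @param embeddings `L x d` matrix of per-position embeddings (`L >= 2`).
#' @return an `L x L x 2d` array.
#' @export
pairwise_feature_map <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  L <- nrow(embeddings)
  d <- ncol(embeddings)
  if (L < 2L) stop_usage("need at least 2 positions")
  out <- array(0, c(L, L, 2L * d))
  for (c in seq_len(d)) {
    out[, , c] <- matrix(embeddings[, c], L, L, byrow = FALSE)
    out[, , d + c] <- matrix(embeddings[, c], L, L, byrow = TRUE)
  }
  out
}

# (L^2) x (2d) matrix of pairwise concat features, rows in column-major (i,j)
# order; cheap flat representation used by the conv head
pairwise_flat <- function(E) {
  L <- nrow(E)
  cbind(E[rep(seq_len(L), times = L), , drop = FALSE],
        E[rep(seq_len(L), each = L), , drop = FALSE])
}

# im2col for a k x k convolution with zero padding over the L x L x C map
pairwise_im2col <- function(E, kernel = 3L) {
  L <- nrow(E)
  P <- pairwise_flat(E)
  C <- ncol(P)
  r <- (kernel - 1L) %/% 2L
  offs <- expand.grid(di = -r:r, dj = -r:r)
  Fm <- matrix(0, L * L, nrow(offs) * C)
  idx_i <- rep(seq_len(L), times = L)
  idx_j <- rep(seq_len(L), each = L)
  for (k in seq_len(nrow(offs))) {
    ii <- idx_i + offs$di[k]
    jj <- idx_j + offs$dj[k]
    ok <- ii >= 1L & ii <= L & jj >= 1L & jj <= L
    src <- (jj[ok] - 1L) * L + ii[ok]
    Fm[which(ok), ((k - 1L) * C + 1L):(k * C)] <- P[src, , drop = FALSE]
  }
  Fm
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# minimal Adam over a flat named list of arrays
small_adam <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

small_adam_step <- function(params, grads, st, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - 0.9^st$t
  bc2 <- 1 - 0.999^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- 0.9 * st$m[[nm]] + 0.1 * g
    st$v[[nm]] <- 0.999 * st$v[[nm]] + 0.001 * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + 1e-8)
  }
  list(params = params, st = st)
}

# two-layer dense net: X -> relu(X W1 + b1) W2 + b2; returns fit utilities
dense_init <- function(d_in, hidden, d_out) {
  list(W1 = matrix(rnorm(d_in * hidden, sd = sqrt(2 / d_in)), d_in, hidden),
       b1 = numeric(hidden),
       W2 = matrix(rnorm(hidden * d_out, sd = sqrt(2 / hidden)), hidden, d_out),
       b2 = numeric(d_out))
}

dense_forward <- function(p, X) {
  H <- relu(sweep(X %*% p$W1, 2, p$b1, "+"))
  list(H = H, out = sweep(H %*% p$W2, 2, p$b2, "+"))
}

# gradient given dOut (same shape as out)
dense_backward <- function(p, X, fw, dOut) {
  dW2 <- t(fw$H) %*% dOut
  db2 <- colSums(dOut)
  dH <- dOut %*% t(p$W2)
  dH[fw$H <= 0] <- 0
  list(W1 = t(X) %*% dH, b1 = colSums(dH), W2 = dW2, b2 = db2)
}

pooled_embeddings <- function(encoder, seqs) {
  t(vapply(seqs, function(s)
    embed_sequence(encoder, encode_nuc(encoder$vocab, s), "mean"),
    numeric(encoder$config$d)))
}

split_holdout <- function(n, holdout) {
  test <- sort(sample.int(n, max(1L, round(holdout * n))))
  list(train = setdiff(seq_len(n), test), test = test)
}

train_pair_head <- function(encoder, fixture, config) {
  X <- cbind(pooled_embeddings(encoder, fixture$records$first),
             pooled_embeddings(encoder, fixture$records$second))
  y <- as.numeric(fixture$labels)
  sp <- split_holdout(nrow(X), config$holdout)
  p <- dense_init(ncol(X), config$hidden, 1L)
  st <- small_adam(p)
  Xtr <- X[sp$train, , drop = FALSE]
  ytr <- y[sp$train]
  for (ep in seq_len(config$epochs)) {
    fw <- dense_forward(p, Xtr)
    pr <- sigmoid(fw$out[, 1])
    dOut <- matrix((pr - ytr) / length(ytr), ncol = 1L)
    gr <- dense_backward(p, Xtr, fw, dOut)
    upd <- small_adam_step(p, gr, st, config$lr)
    p <- upd$params
    st <- upd$st
  }
  pred <- as.numeric(sigmoid(dense_forward(p, X[sp$test, , drop = FALSE])$out) > 0.5)
  acc <- mean(pred == y[sp$test])
  baseline <- max(mean(y[sp$test]), 1 - mean(y[sp$test]))
  list(params = p,
       metrics = list(accuracy = acc, baseline_accuracy = baseline,
                      n_test = length(sp$test)))
}

train_cls_head <- function(encoder, fixture, config) {
  X <- pooled_embeddings(encoder, fixture$records)
  y <- as.integer(factor(fixture$labels))
  k <- max(y)
  sp <- split_holdout(nrow(X), config$holdout)
  p <- dense_init(ncol(X), config$hidden, k)
  st <- small_adam(p)
  Xtr <- X[sp$train, , drop = FALSE]
  ytr <- y[sp$train]
  onehot <- diag(k)[ytr, , drop = FALSE]
  for (ep in seq_len(config$epochs)) {
    fw <- dense_forward(p, Xtr)
    Z <- fw$out - apply(fw$out, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    gr <- dense_backward(p, Xtr, fw, (P - onehot) / nrow(Xtr))
    upd <- small_adam_step(p, gr, st, config$lr)
    p <- upd$params
    st <- upd$st
  }
  pred <- max.col(dense_forward(p, X[sp$test, , drop = FALSE])$out)
  acc <- mean(pred == y[sp$test])
  baseline <- max(table(y[sp$test])) / length(sp$test)
  list(params = p,
       metrics = list(accuracy = acc, baseline_accuracy = baseline,
                      n_test = length(sp$test)))
}

# shared machinery for the two pairwise-map heads. Features per cell (i, j):
# outer-product (bilinear) channels of a fixed seeded k-dim projection of
# the two position embeddings, taken at the `kernel` taps along the
# anti-diagonal (the direction along which base-pair stems stack). The
# bilinear channels matter: base pairing is a bilinear relation between the
# two position embeddings with no linear trace in concatenated features, so
# a purely concat-fed head starts on a gradient plateau and does not train
# at this scale. The map itself is a single linear convolution kernel over
# these channels, fit as a ridge-penalized GLM.
map_projection <- function(d, k = 24L) {
  k <- min(d, k)
  with_seed(172001L, matrix(rnorm(d * k, sd = 1 / sqrt(d)), d, k))
}

map_features <- function(E, kernel, P) {
  L <- nrow(E)
  V <- E %*% P
  k <- ncol(P)
  A <- V[rep(seq_len(L), times = L), , drop = FALSE]
  B <- V[rep(seq_len(L), each = L), , drop = FALSE]
  OP <- A[, rep(seq_len(k), times = k)] * B[, rep(seq_len(k), each = k)]
  r <- (kernel - 1L) %/% 2L
  taps <- -r:r # kernel taps along the anti-diagonal (stem) direction
  Fo <- matrix(0, L * L, length(taps) * k * k)
  idx_i <- rep(seq_len(L), times = L)
  idx_j <- rep(seq_len(L), each = L)
  for (q in seq_along(taps)) {
    ii <- idx_i + taps[q]
    jj <- idx_j - taps[q]
    ok <- ii >= 1L & ii <= L & jj >= 1L & jj <= L
    Fo[which(ok), ((q - 1L) * k * k + 1L):(q * k * k)] <-
      OP[(jj[ok] - 1L) * L + ii[ok], , drop = FALSE]
  }
  Fo
}

upper_idx <- function(L) which(upper.tri(matrix(0, L, L)))

# symmetrize per-cell features and keep upper-triangle rows: because the
# model is linear, averaging the (i,j) and (j,i) feature rows is exactly
# logit symmetrization
sym_upper_features <- function(Fm, L) {
  transpose_order <- as.vector(t(matrix(seq_len(L * L), L, L)))
  ((Fm + Fm[transpose_order, , drop = FALSE]) / 2)[upper_idx(L), , drop = FALSE]
}

.MAP_RIDGE_LAMBDA <- 0.001

train_map_head <- function(encoder, fixture, config, task) {
  P <- map_projection(encoder$config$d)
  states <- lapply(fixture$records, function(s)
    encoder_states(encoder, encode_nuc(encoder$vocab, s)))
  feats <- lapply(states, function(E)
    sym_upper_features(map_features(E, config$kernel, P), nrow(E)))
  n <- length(states)
  sp <- split_holdout(n, config$holdout)

  X <- do.call(rbind, feats[sp$train])
  y <- unlist(lapply(sp$train, function(i) {
    M <- fixture$labels[[i]]
    M[upper.tri(M)]
  }))
  lam_path <- c(0.1, 0.01, .MAP_RIDGE_LAMBDA)
  if (task == "pairing") {
    pos_weight <- max(1, (length(y) - sum(y)) / max(1, sum(y)))
    w <- ifelse(y == 1, pos_weight, 1)
    fit <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                          alpha = 0, lambda = lam_path, standardize = TRUE)
  } else {
    fit <- glmnet::glmnet(X, y, family = "gaussian",
                          alpha = 0, lambda = lam_path, standardize = TRUE)
  }
  predict_map <- function(E) {
    L <- nrow(E)
    Fs <- sym_upper_features(map_features(E, config$kernel, P), L)
    v <- as.numeric(glmnet::predict.glmnet(fit, Fs, s = .MAP_RIDGE_LAMBDA))
    S <- matrix(0, L, L)
    S[upper_idx(L)] <- v
    S + t(S)
  }
  p <- fit
  if (task == "pairing") {
    f1s <- vapply(sp$test, function(i) {
      S <- sigmoid(predict_map(states[[i]]))
      structure_f1(S, fixture$labels[[i]])["f1"]
    }, numeric(1))
    metrics <- list(mean_f1 = mean(f1s), baseline_f1 = 0,
                    n_test = length(sp$test))
  } else {
    preds <- unlist(lapply(sp$test, function(i) {
      S <- predict_map(states[[i]])
      pmax(S, 0)[upper_idx(nrow(S))]
    }))
    truths <- unlist(lapply(sp$test, function(i)
      fixture$labels[[i]][upper_idx(nrow(fixture$labels[[i]]))]))
    metrics <- list(r2 = r2_score(preds, truths), baseline_r2 = 0,
                    n_test = length(sp$test))
  }
  list(params = p, metrics = metrics, predict_map = predict_map)
}

train_torsion_head <- function(encoder, fixture, config) {
  states <- lapply(fixture$records, function(s)
    encoder_states(encoder, encode_nuc(encoder$vocab, s)))
  sp <- split_holdout(length(states), config$holdout)
  X <- do.call(rbind, states[sp$train])
  Y <- do.call(rbind, lapply(fixture$labels[sp$train], encode_angles))
  Xv <- do.call(rbind, states[sp$test])
  Yv_ang <- do.call(rbind, fixture$labels[sp$test])
  Yv <- encode_angles(Yv_ang)
  p <- dense_init(ncol(X), config$hidden, 14L)
  st <- small_adam(p)
  val_mse <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fw <- dense_forward(p, X)
    gr <- dense_backward(p, X, fw, 2 * (fw$out - Y) / length(Y))
    upd <- small_adam_step(p, gr, st, config$lr)
    p <- upd$params
    st <- upd$st
    val_mse[ep] <- mean((dense_forward(p, Xv)$out - Yv)^2)
  }
  pred_ang <- decode_angles(dense_forward(p, Xv)$out)
  mae <- circular_mae(pred_ang, Yv_ang)
  # baseline: per-angle circular mean of the training targets
  Ytr_ang <- do.call(rbind, fixture$labels[sp$train])
  base_ang <- vapply(seq_len(7L), function(j) {
    rad <- Ytr_ang[, j] * pi / 180
    atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  }, numeric(1))
  base_pred <- matrix(base_ang, nrow(Yv_ang), 7L, byrow = TRUE)
  list(params = p,
       metrics = list(val_mse = val_mse, mae_degrees = mae,
                      baseline_mae_degrees = circular_mae(base_pred, Yv_ang),
                      n_test = length(sp$test)))
}

#' Train a fine-tuning head on a frozen backbone
#'
#' The encoder provides features only and is never modified. Architectures:
#' sequence-pair interaction and sequence classification use concatenated
#' mean-pooled embeddings through a small dense classifier. The pairing-map
#' head is a single linear convolution kernel over pairwise bilinear
#' (outer-product) channels of the two position embeddings, taken at the
#' kernel taps along the anti-diagonal; it predicts the upper triangle of
#' the contact matrix with logits symmetrized by averaging with their
#' transpose, fit as a ridge-penalized weighted logistic model. The
#' distance-map head shares that featurization with a zero-clamped ridge
#' regression output. The torsion head maps each position's embedding
#' through a dense layer to 14 sine/cosine outputs trained with mean
#' squared error.
#'
#' @param encoder a (frozen) `rna_encoder`.
#' @param fixture a `task_fixture` from [generate_task_fixture()] or
#'   [read_fixture()].
#' @param config a [head_config()].
#' @return an `rna_head` with elements `kind`, `params`, `metrics` (held-out
#'   metrics incl. the trivial baseline for the task), and `config`.
#' @export
train_head <- function(encoder, fixture, config = head_config()) {
  stopifnot(inherits(encoder, "rna_encoder"), inherits(fixture, "task_fixture"),
            inherits(config, "head_config"))
  res <- with_seed(config$seed, {
    switch(fixture$kind,
           pair_interaction = train_pair_head(encoder, fixture, config),
           seq_classification = train_cls_head(encoder, fixture, config),
           pairing_map = train_map_head(encoder, fixture, config, "pairing"),
           distance_map = train_map_head(encoder, fixture, config, "distance"),
           torsion_angles = train_torsion_head(encoder, fixture, config),
           stop_usage("unsupported fixture kind: ", fixture$kind))
  })
  structure(c(res, list(kind = fixture$kind, config = config)),
            class = "rna_head")
}

# ---- metrics -----------------------------------------------------------------

#' Precision, recall and F1 over unordered position pairs
#'
#' Predictions are binarized at `threshold` and compared with the binary
#' truth over pairs `i < j`. Zero denominators yield 0, except that a
#' perfect-empty prediction (no true and no predicted pairs) scores F1 = 1.
#'
#' @param predicted `L x L` numeric matrix (probabilities or binary).
#' @param truth `L x L` binary matrix.
#' @param threshold binarization threshold, default 0.5.
#' @return named numeric vector `(precision, recall, f1)`.
#' @export
structure_f1 <- function(predicted, truth, threshold = 0.5) {
  if (!all(dim(predicted) == dim(truth)))
    stop_usage("predicted and truth shapes differ")
  ui <- upper.tri(truth)
  p <- predicted[ui] > threshold
  t <- truth[ui] > 0.5
  tp <- sum(p & t)
  np <- sum(p)
  nt <- sum(t)
  if (nt == 0 && np == 0)
    return(c(precision = 1, recall = 1, f1 = 1))
  prec <- if (np == 0) 0 else tp / np
  rec <- if (nt == 0) 0 else tp / nt
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

#' Encode / decode torsion angles as sine-cosine pairs
#'
#' Seven angles per position become 14 values ordered `(sin, cos)` per angle;
#' decoding uses the two-argument arctangent and returns degrees in
#' (-180, 180].
#'
#' @param angles `n x 7` matrix of angles in degrees.
#' @param sin_cos `n x 14` matrix of interleaved sine/cosine values.
#' @return the complementary representation.
#' @export
encode_angles <- function(angles) {
  rad <- as.matrix(angles) * pi / 180
  out <- matrix(0, nrow(rad), 14L)
  out[, seq(1, 13, by = 2)] <- sin(rad)
  out[, seq(2, 14, by = 2)] <- cos(rad)
  out
}

#' @rdname encode_angles
#' @export
decode_angles <- function(sin_cos) {
  sin_cos <- as.matrix(sin_cos)
  s <- sin_cos[, seq(1, 13, by = 2), drop = FALSE]
  c <- sin_cos[, seq(2, 14, by = 2), drop = FALSE]
  if (any(s == 0 & c == 0))
    stop_usage("undefined angle: sine and cosine both zero")
  ang <- atan2(s, c) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Circular mean absolute error in degrees
#'
#' Per-entry error is `min(|delta|, 360 - |delta|)`, averaged over all
#' positions and angles, so a prediction of 179 degrees against a truth of
#' -179 degrees errs by 2 degrees, not 358.
#'
#' @param pred,truth matrices of angles in degrees, same shape.
#' @return mean circular absolute error in degrees.
#' @export
circular_mae <- function(pred, truth) {
  d <- abs(as.matrix(pred) - as.matrix(truth))
  mean(pmin(d, 360 - d))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` of predictions against a non-constant truth.
#'
#' @param predicted,truth numeric vectors of equal length (`>= 2`).
#' @return the R-squared value (can be negative).
#' @export
r2_score <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 2L)
    stop_usage("need equal-length vectors with >= 2 entries")
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) stop_usage("undefined score: constant truth")
  1 - sum((predicted - truth)^2) / ss_tot
}
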