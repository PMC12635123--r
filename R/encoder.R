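# Compact bidirectional transformer encoder with ALiBi distance penalties.
# The numerical core (forward pass and analytic backpropagation) lives in
# src/encoder.cpp; this file owns configuration, initialization, and the
# user-facing forward/embedding operations.

#' Encoder configuration
#'
#' Desk-scale defaults: 2 layers, 4 heads, hidden dimension 64, feed-forward
#' 256. The architecture is expressible at any scale through these fields.
#' Pre-layer normalization, GELU feed-forward, learned token embeddings tied
#' to the output projection, and no positional signal other than the ALiBi
#' attention bias.
#'
#' @param n_layers,n_heads,d,d_ff,vocab_size architecture sizes; `d` must be
#'   divisible by `n_heads`.
#' @param dropout retained for configuration compatibility; this compact
#'   encoder is dropout-free (all evaluation is deterministic), and a nonzero
#'   value is rejected.
#' @param seed initialization seed.
#' @return a `model_config`.
#' @export
model_config <- function(n_layers = 2L, n_heads = 4L, d = 64L, d_ff = 256L,
                         vocab_size, dropout = 0, seed = 0L) {
  if (any(c(n_layers, n_heads, d, d_ff, vocab_size) < 1L))
    stop_usage("all sizes must be >= 1")
  if (d %% n_heads != 0L)
    stop_usage("hidden dimension d must be divisible by n_heads")
  if (dropout != 0)
    stop_usage("this encoder implementation is dropout-free; set dropout = 0")
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 d = as.integer(d), d_ff = as.integer(d_ff),
                 vocab_size = as.integer(vocab_size), dropout = dropout,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' ALiBi head slopes
#'
#' For 8 heads the slopes are exactly the geometric progression 1/2, 1/2^2,
#' ..., 1/2^8; in general `slope_h = 2^(-8h/n)` for `h = 1..n`, which
#' preserves those values at `n = 8`.
#'
#' @param n_heads number of attention heads (`>= 1`).
#' @return numeric vector of positive slopes, one per head.
#' @export
alibi_slopes <- function(n_heads) {
  if (n_heads < 1L) stop_usage("n_heads must be >= 1")
  2^(-8 * seq_len(n_heads) / n_heads)
}

#' ALiBi bias matrix
#'
#' Entry `(i, j)` equals `slope * |i - j|`; the matrix is subtracted from the
#' scaled dot-product attention logits (`A_ij = Q_i K_j' / sqrt(d) - b_ij`).
#' The formula is length-free, which is what lets the encoder run at lengths
#' far beyond any seen in training.
#'
#' @param L sequence length.
#' @param slope positive head slope.
#' @return an `L x L` symmetric matrix with zero diagonal.
#' @export
alibi_bias_matrix <- function(L, slope) {
  if (L < 1L) stop_usage("L must be >= 1")
  if (slope <= 0) stop_usage("slope must be positive")
  idx <- seq_len(L)
  slope * abs(outer(idx, idx, "-"))
}

param_shapes <- function(config) {
  d <- config$d; ff <- config$d_ff; V <- config$vocab_size
  shapes <- list(emb = c(V, d), out_b = V, lnf_g = d, lnf_b = d)
  for (l in seq_len(config$n_layers)) {
    p <- paste0("l", l, ".")
    shapes[[paste0(p, "ln1_g")]] <- d
    shapes[[paste0(p, "ln1_b")]] <- d
    shapes[[paste0(p, "Wq")]] <- c(d, d)
    shapes[[paste0(p, "Wk")]] <- c(d, d)
    shapes[[paste0(p, "Wv")]] <- c(d, d)
    shapes[[paste0(p, "Wo")]] <- c(d, d)
    shapes[[paste0(p, "ln2_g")]] <- d
    shapes[[paste0(p, "ln2_b")]] <- d
    shapes[[paste0(p, "W1")]] <- c(d, ff)
    shapes[[paste0(p, "b1")]] <- ff
    shapes[[paste0(p, "W2")]] <- c(ff, d)
    shapes[[paste0(p, "b2")]] <- d
  }
  shapes
}

#' Initialize an encoder
#'
#' Weights are drawn N(0, 0.02^2), layer-norm gains start at 1 and all biases
#' at 0; reproducible given the seed.
#'
#' @param config a [model_config()]; its `vocab_size` must cover `vocab`.
#' @param vocab the shared `rna_vocabulary`.
#' @param seed optional override of `config$seed`.
#' @return an `rna_encoder` handle (parameters, config, vocabulary, slopes).
#' @export
init_encoder <- function(config, vocab, seed = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(vocab, "rna_vocabulary"))
  if (config$vocab_size < length(vocab))
    stop_usage("config vocab_size smaller than vocabulary")
  seed <- seed %||% config$seed
  params <- with_seed(seed, {
    lapply(param_shapes(config), function(sh) {
      if (length(sh) == 2L) {
        matrix(rnorm(prod(sh), sd = 0.02), sh[1], sh[2])
      } else {
        numeric(sh)
      }
    })
  })
  for (nm in names(params)) {
    if (grepl("ln.+_g$|lnf_g$", nm)) params[[nm]] <- params[[nm]] + 1
  }
  structure(list(params = params, config = config, vocab = vocab,
                 slopes = alibi_slopes(config$n_heads)),
            class = "rna_encoder")
}

#' @export
print.rna_encoder <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("rna_encoder: %d layers, %d heads, d=%d, vocab=%d (%s parameters)\n",
              x$config$n_layers, x$config$n_heads, x$config$d,
              x$config$vocab_size, format(n_par, big.mark = ",")))
  invisible(x)
}

check_ids <- function(encoder, ids) {
  if (length(ids) == 0L) stop_usage("empty token sequence")
  if (any(ids < 1L) || any(ids > encoder$config$vocab_size))
    stop_usage("token id outside vocabulary (integrity error)")
}

#' Masked-LM forward pass
#'
#' Returns the per-position probability distribution over the vocabulary.
#' Deterministic given fixed parameters.
#'
#' @param encoder an `rna_encoder`.
#' @param token_seq a `token_seq` (or bare id vector).
#' @return a `length x vocab_size` matrix; every row is nonnegative and sums
#'   to 1.
#' @export
forward_mlm <- function(encoder, token_seq) {
  ids <- if (inherits(token_seq, "token_seq")) token_seq$ids else as.integer(token_seq)
  check_ids(encoder, ids)
  cpp_forward_probs(encoder$params, encoder$config$n_layers,
                    encoder$config$n_heads, ids, encoder$slopes)
}

#' Final-layer hidden states
#'
#' @inheritParams forward_mlm
#' @return a `length x d` matrix of layer-normalized final states.
#' @export
encoder_states <- function(encoder, token_seq) {
  ids <- if (inherits(token_seq, "token_seq")) token_seq$ids else as.integer(token_seq)
  check_ids(encoder, ids)
  cpp_forward_states(encoder$params, encoder$config$n_layers,
                     encoder$config$n_heads, ids, encoder$slopes)
}

#' Pooled sequence embedding
#'
#' `"mean"` averages final-layer states over non-special positions; `"cls"`
#' prepends a CLS token and returns its final state.
#'
#' @inheritParams forward_mlm
#' @param pooling `"mean"` or `"cls"`.
#' @return numeric vector of length `d`.
#' @export
embed_sequence <- function(encoder, token_seq, pooling = c("mean", "cls")) {
  pooling <- match.arg(pooling)
  ids <- if (inherits(token_seq, "token_seq")) token_seq$ids else as.integer(token_seq)
  if (pooling == "cls") {
    states <- encoder_states(encoder, c(cls_id(encoder$vocab), ids))
    return(states[1L, ])
  }
  keep <- !(ids %in% special_ids(encoder$vocab))
  if (!any(keep))
    stop_usage("degenerate input: no non-special positions to pool over")
  states <- encoder_states(encoder, ids)
  colMeans(states[keep, , drop = FALSE])
}

#' Save / load an encoder checkpoint
#'
#' A self-describing container holding the configuration, the vocabulary and
#' a hash of it, and all parameters.
#'
#' @param encoder an `rna_encoder`.
#' @param path checkpoint path.
#' @export
save_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "rna_encoder"))
  obj <- list(format = "rnalm-encoder", version = 1L,
              config = encoder$config, vocab = encoder$vocab,
              vocab_hash = vocab_hash(encoder$vocab),
              params = encoder$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rnalm-encoder"))
    stop_usage("not an encoder checkpoint: ", path)
  if (!identical(obj$vocab_hash, vocab_hash(obj$vocab)))
    stop_usage("checkpoint vocabulary hash mismatch")
  structure(list(params = obj$params, config = obj$config, vocab = obj$vocab,
                 slopes = alibi_slopes(obj$config$n_heads)),
            class = "rna_encoder")
}

vocab_hash <- function(vocab) {
  s <- paste(vocab$tokens, collapse = "\x01")
  # small rolling hash; stable across platforms
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  h
}
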