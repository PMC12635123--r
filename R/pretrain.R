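# Masking, dual-stream batching, the combined masked-LM loss, and a seeded
# Adam training loop with linear warmup / linear decay.

#' Masking policy
#'
#' `"random"` masks `round(rate * n)` non-special positions (at least one
#' when `rate > 0`) chosen without replacement; `"central"` masks exactly the
#' central token, position `floor(n/2)` 0-based. Selected tokens are replaced
#' with `[MASK]` under the default `"pure-mask"` strategy; the BERT-style
#' `"bert-80-10-10"` replacement (80% mask, 10% random token, 10% unchanged)
#' is available by configuration.
#'
#' @param protocol `"random"` or `"central"`.
#' @param rate masking fraction in `[0, 1]` (random protocol; default 0.15).
#' @param replacement `"pure-mask"` or `"bert-80-10-10"`.
#' @param seed optional integer; when given, masking uses a private RNG
#'   stream seeded with it, otherwise the current RNG state.
#' @return a `masking_policy`.
#' @export
masking_policy <- function(protocol = c("random", "central"), rate = 0.15,
                           replacement = c("pure-mask", "bert-80-10-10"),
                           seed = NULL) {
  protocol <- match.arg(protocol)
  replacement <- match.arg(replacement)
  if (rate < 0 || rate > 1) stop_usage("rate must be in [0, 1]")
  structure(list(protocol = protocol, rate = rate, replacement = replacement,
                 seed = seed),
            class = "masking_policy")
}

mask_tokens_impl <- function(ids, policy, vocab) {
  n <- length(ids)
  if (n < 1L) stop_usage("token count must be >= 1")
  maskable <- which(!(ids %in% special_ids(vocab)))
  if (policy$protocol == "central") {
    pos <- floor(n / 2) + 1L
    if (ids[pos] %in% special_ids(vocab))
      stop_usage("central position is a special token")
    sel <- pos
  } else {
    if (policy$rate == 0) {
      sel <- integer(0)
    } else {
      if (length(maskable) == 0L)
        stop_usage("degenerate input: no maskable (non-special) position")
      k <- max(1L, round(policy$rate * length(maskable)))
      sel <- sort(sample(maskable, min(k, length(maskable))))
    }
  }
  targets <- ids[sel]
  out <- ids
  if (length(sel) > 0L) {
    if (policy$replacement == "pure-mask") {
      out[sel] <- mask_id(vocab)
    } else {
      u <- runif(length(sel))
      repl <- ifelse(u < 0.8, mask_id(vocab),
                     ifelse(u < 0.9,
                            sample(setdiff(seq_along(vocab$tokens),
                                           special_ids(vocab)),
                                   length(sel), replace = TRUE),
                            ids[sel]))
      out[sel] <- repl
    }
  }
  list(ids_masked = out, positions = sel, targets = targets)
}

#' Mask tokens of a sequence
#'
#' Special tokens are never masked; targets record the pre-mask tokens.
#'
#' @param token_seq a `token_seq`.
#' @param policy a [masking_policy()].
#' @param vocab the `rna_vocabulary`.
#' @return a `masked_seq`: masked ids, 1-based masked positions, targets,
#'   and the scheme tag.
#' @export
mask_tokens <- function(token_seq, policy, vocab) {
  stopifnot(inherits(token_seq, "token_seq"), inherits(policy, "masking_policy"))
  run <- function() mask_tokens_impl(token_seq$ids, policy, vocab)
  m <- if (!is.null(policy$seed)) with_seed(policy$seed, run()) else run()
  structure(c(m, list(scheme = token_seq$scheme)), class = "masked_seq")
}

#' Dual-stream batch iterator
#'
#' Every source sequence contributes one NUC-masked and one BPE-masked view
#' per epoch; iteration order is a seeded permutation, identical across the
#' two streams so the same underlying chunks appear in both.
#'
#' @param corpus named character vector of normalized sequences.
#' @param bpe_model a trained `bpe_model` (its vocabulary is shared by both
#'   streams).
#' @param policy a [masking_policy()].
#' @param batch_size sequences per batch.
#' @param epochs number of passes.
#' @param seed integer seed controlling shuffling and mask sampling.
#' @return list of batches; each batch holds parallel `nuc` and `bpe`
#'   elements (`seqs`, `mask_pos`, `targets`) over the same source records.
#' @export
dual_batch_iterator <- function(corpus, bpe_model, policy, batch_size = 32L,
                                epochs = 1L, seed = 0L) {
  if (length(corpus) == 0L) stop_usage("corpus must be non-empty")
  vocab <- bpe_model$vocab
  nuc_ids <- lapply(corpus, function(s) encode_nuc(vocab, s)$ids)
  bpe_ids <- lapply(corpus, function(s) encode_bpe(bpe_model, s)$ids)
  with_seed(seed, {
    batches <- list()
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(corpus))
      starts <- seq(1L, length(ord), by = batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + batch_size - 1L, length(ord))]
        mk <- function(idlist) {
          ms <- lapply(idlist[idx], mask_tokens_impl, policy = policy,
                       vocab = vocab)
          list(seqs = lapply(ms, `[[`, "ids_masked"),
               mask_pos = lapply(ms, `[[`, "positions"),
               targets = lapply(ms, `[[`, "targets"))
        }
        batches[[length(batches) + 1L]] <-
          list(epoch = ep, indices = idx, nuc = mk(nuc_ids), bpe = mk(bpe_ids))
      }
    }
    batches
  })
}

stream_loss <- function(encoder, stream, want_grad = FALSE) {
  cpp_mlm_batch(encoder$params, encoder$config$n_layers,
                encoder$config$n_heads, encoder$slopes,
                unname(stream$seqs), unname(stream$mask_pos),
                unname(stream$targets), want_grad)
}

#' Combined dual masked-LM loss
#'
#' The total loss is the sum of the BPE-stream and NUC-stream masked-LM
#' losses, each `-sum log2 p(true token | masked sequence)` over its masked
#' set, in bits. One parameter set serves both streams.
#'
#' @param encoder an `rna_encoder`.
#' @param nuc_batch,bpe_batch stream elements from [dual_batch_iterator()].
#' @return total loss in bits (nonnegative).
#' @export
dual_mlm_loss <- function(encoder, nuc_batch, bpe_batch) {
  n_nuc <- sum(lengths(nuc_batch$mask_pos))
  n_bpe <- sum(lengths(bpe_batch$mask_pos))
  if (n_nuc + n_bpe == 0L)
    stop_usage("degenerate input: both masked sets are empty")
  stream_loss(encoder, nuc_batch)$loss_bits +
    stream_loss(encoder, bpe_batch)$loss_bits
}

#' Training configuration
#'
#' Full-scale defaults: peak learning rate 2e-4, warmup over 6% of steps,
#' linear decay to 2% of the peak. Desk-scale runs typically override the
#' learning rate, batch size and epoch count.
#'
#' @param lr peak learning rate.
#' @param warmup_ratio fraction of steps spent in linear warmup, in `[0, 1)`.
#' @param final_lr_frac fraction of the peak reached at the final step.
#' @param batch_size,epochs,seed usual meanings.
#' @param mixing stream mixing rule; `"alternate"` (default) alternates
#'   optimizer steps between the NUC and BPE views of each batch.
#' @param grad_clip global gradient-norm clip.
#' @return a `train_config`.
#' @export
train_config <- function(lr = 2e-4, warmup_ratio = 0.06, final_lr_frac = 0.02,
                         batch_size = 200L, epochs = 2L, seed = 0L,
                         mixing = "alternate", grad_clip = 1.0) {
  if (lr <= 0 || batch_size < 1 || epochs < 1 || grad_clip <= 0 ||
      final_lr_frac <= 0)
    stop_usage("lr, batch_size, epochs, grad_clip, final_lr_frac must be positive")
  if (warmup_ratio < 0 || warmup_ratio >= 1)
    stop_usage("warmup_ratio must be in [0, 1)")
  if (!identical(mixing, "alternate"))
    stop_usage("only the 'alternate' mixing rule is implemented")
  structure(list(lr = lr, warmup_ratio = warmup_ratio,
                 final_lr_frac = final_lr_frac,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 mixing = mixing, grad_clip = grad_clip),
            class = "train_config")
}

#' Learning rate at a given optimizer step
#'
#' Linear warmup from 0 over `warmup_ratio` of the run, then linear decay to
#' `final_lr_frac * lr` at the last step. Step 0 has rate 0; the end of
#' warmup has the peak rate.
#'
#' @param step 0-based optimizer step.
#' @param total_steps total number of optimizer steps.
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_at_step <- function(step, total_steps, config) {
  warm <- floor(config$warmup_ratio * total_steps)
  if (warm > 0 && step < warm) return(config$lr * step / warm)
  if (total_steps <= warm) return(config$lr)
  frac <- (step - warm) / (total_steps - warm)
  config$lr * (1 - (1 - config$final_lr_frac) * frac)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Dual-tokenization masked-LM pretraining
#'
#' Optimizes a single parameter set on alternating NUC and BPE masked
#' batches with Adam, linear warmup and linear decay, and global gradient
#' clipping. Fully seeded; aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param corpus named character vector of normalized sequences.
#' @param bpe_model a trained `bpe_model`.
#' @param config a [model_config()]; `vocab_size` must cover the model's
#'   vocabulary.
#' @param tconfig a [train_config()].
#' @param policy a [masking_policy()] (default random 15%).
#' @param checkpoint_dir if non-NULL, a checkpoint is written there after
#'   each epoch.
#' @return a `pretrain_result`: the trained `rna_encoder` and a training log
#'   `data.frame(step, epoch, scheme, loss_bits, lr)` with loss in bits per
#'   masked token.
#' @export
pretrain <- function(corpus, bpe_model, config, tconfig,
                     policy = masking_policy("random", 0.15),
                     checkpoint_dir = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(tconfig, "train_config"))
  encoder <- init_encoder(config, bpe_model$vocab)
  batches <- dual_batch_iterator(corpus, bpe_model, policy,
                                 batch_size = tconfig$batch_size,
                                 epochs = tconfig$epochs, seed = tconfig$seed)
  total_steps <- 2L * length(batches)
  state <- adam_init(encoder$params)
  log <- vector("list", total_steps)
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  step <- 0L
  last_epoch <- 1L
  for (b in batches) {
    if (!is.null(checkpoint_dir) && b$epoch > last_epoch) {
      save_encoder(encoder,
                   file.path(checkpoint_dir,
                             sprintf("encoder_epoch%03d.rds", last_epoch)))
      last_epoch <- b$epoch
    }
    for (scheme in c("nuc", "bpe")) {
      lr <- lr_at_step(step, total_steps, tconfig)
      res <- stream_loss(encoder, b[[scheme]], want_grad = TRUE)
      n_masked <- max(1, res$n_masked)
      loss <- res$loss_bits / n_masked
      if (!is.finite(loss))
        stop("training diverged: non-finite loss at step ", step,
             " (scheme ", scheme, ")", call. = FALSE)
      grads <- lapply(res$grads, function(g) g / n_masked)
      if (lr > 0) {
        upd <- adam_step(encoder$params, grads, state, lr, tconfig$grad_clip)
        encoder$params <- upd$params
        state <- upd$state
      }
      step <- step + 1L
      log[[step]] <- data.frame(step = step, epoch = b$epoch,
                                scheme = toupper(scheme), loss_bits = loss,
                                lr = lr)
    }
  }
  log <- do.call(rbind, log)
  if (!is.null(checkpoint_dir)) {
    save_encoder(encoder,
                 file.path(checkpoint_dir,
                           sprintf("encoder_epoch%03d.rds", last_epoch)))
    save_encoder(encoder, file.path(checkpoint_dir, "encoder_final.rds"))
  }
  structure(list(encoder = encoder, log = log), class = "pretrain_result")
}
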