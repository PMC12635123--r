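# Masked-LM perplexity / token-recovery evaluation and silhouette-based
# clustering evaluation of pooled embeddings.

scheme_subvocab <- function(vocab, scheme) {
  if (scheme == "NUC") vocab$base_ids
  else setdiff(seq_along(vocab$tokens), special_ids(vocab))
}

#' Masked-LM perplexity and recovery accuracy
#'
#' For each sequence, masks positions per the protocol, obtains the model's
#' probability at every masked site, and reports the average negative log2
#' probability `l`, the perplexity `2^l`, and the recovery accuracy (fraction
#' of masked sites whose argmax prediction equals the true token). Perplexity
#' is computed per sequence and pooled over all masked positions.
#'
#' With `restrict_vocab = TRUE` both the normalization and the argmax are
#' limited to the scheme's sub-vocabulary (the 4 bases for NUC; all
#' non-special tokens for BPE), which moves chance-level accuracy from about
#' 1/vocab to about 1/4 for nucleotide models.
#'
#' `encoder = NULL` evaluates the forced-uniform baseline predictor, whose
#' perplexity equals the effective vocabulary size exactly -- the chance
#' calibration every trained model should beat.
#'
#' @param encoder an `rna_encoder`, or `NULL` for the uniform baseline.
#' @param sequences character vector of normalized sequences.
#' @param scheme `"NUC"` or `"BPE"`.
#' @param protocol `"random"` (default 15%) or `"central"`.
#' @param rate masking rate for the random protocol.
#' @param restrict_vocab restrict normalization and argmax to the scheme's
#'   sub-vocabulary.
#' @param bpe_model required: supplies the vocabulary (and the merges when
#'   `scheme = "BPE"`).
#' @param seed seed for mask sampling.
#' @return a `perplexity_report`: per-sequence data frame (`loss_bits`,
#'   `perplexity`, `accuracy`, `n_masked`), pooled loss/perplexity/accuracy,
#'   and the protocol descriptor.
#' @export
masked_lm_eval <- function(encoder, sequences, scheme = c("NUC", "BPE"),
                           protocol = c("random", "central"), rate = 0.15,
                           restrict_vocab = FALSE, bpe_model = NULL,
                           seed = 0L) {
  scheme <- match.arg(scheme)
  protocol <- match.arg(protocol)
  if (length(sequences) == 0L) stop_usage("empty sequence set")
  if (is.null(bpe_model)) stop_usage("bpe_model is required for tokenization")
  vocab <- bpe_model$vocab
  vocab_size <- if (is.null(encoder)) length(vocab) else encoder$config$vocab_size
  sub <- scheme_subvocab(vocab, scheme)
  policy <- masking_policy(protocol, rate)

  with_seed(seed, {
    per <- lapply(sequences, function(s) {
      ts <- if (scheme == "NUC") encode_nuc(vocab, s) else encode_bpe(bpe_model, s)
      m <- mask_tokens(ts, policy, vocab)
      if (length(m$positions) == 0L) return(NULL)
      if (is.null(encoder)) {
        k <- if (restrict_vocab) length(sub) else vocab_size
        p_true <- rep(1 / k, length(m$positions))
        pred_ok <- rep(1 / k, length(m$positions)) # expected chance accuracy
      } else {
        probs <- forward_mlm(encoder, m$ids_masked)
        rows <- probs[m$positions, , drop = FALSE]
        if (restrict_vocab) {
          rows <- rows[, sub, drop = FALSE]
          rows <- rows / rowSums(rows)
          tgt <- match(m$targets, sub)
        } else {
          tgt <- m$targets
        }
        p_true <- rows[cbind(seq_len(nrow(rows)), tgt)]
        pred_ok <- as.numeric(max.col(rows, ties.method = "first") == tgt)
      }
      loss <- mean(-log2(p_true))
      data.frame(loss_bits = loss, perplexity = 2^loss,
                 accuracy = mean(pred_ok), n_masked = length(m$positions),
                 sum_nll = sum(-log2(p_true)), sum_acc = sum(pred_ok))
    })
    per <- do.call(rbind, per)
    if (is.null(per)) stop_usage("no maskable positions in any sequence")
    pooled_loss <- sum(per$sum_nll) / sum(per$n_masked)
    structure(list(per_sequence = per[, c("loss_bits", "perplexity",
                                          "accuracy", "n_masked")],
                   mean_loss_bits = pooled_loss,
                   perplexity = 2^pooled_loss,
                   accuracy = sum(per$sum_acc) / sum(per$n_masked),
                   protocol = protocol, rate = rate, scheme = scheme,
                   restrict_vocab = restrict_vocab),
              class = "perplexity_report")
  })
}

#' @export
print.perplexity_report <- function(x, ...) {
  cat(sprintf("masked-LM eval (%s, %s%s): perplexity %.4f, accuracy %.4f over %d masked tokens\n",
              x$scheme, x$protocol,
              if (x$restrict_vocab) ", restricted vocab" else "",
              x$perplexity, x$accuracy, sum(x$per_sequence$n_masked)))
  invisible(x)
}

pairwise_dist <- function(points, metric) {
  if (metric == "euclidean") return(as.matrix(dist(points)))
  nrm <- sqrt(rowSums(points^2))
  nrm[nrm == 0] <- 1
  sim <- (points / nrm) %*% t(points / nrm)
  D <- 1 - sim
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Silhouette coefficient of a labeled point set
#'
#' For point `i`, `a(i)` is the mean distance to the other members of its
#' cluster, `b(i)` the minimum over other clusters of the mean distance to
#' that cluster, and `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Values near 1
#' mean the point sits well inside its cluster; 0 means it lies on the
#' decision boundary; negative values suggest misassignment. Singleton
#' clusters score 0 by convention.
#'
#' @param points numeric matrix, one row per point.
#' @param labels cluster labels (any atomic type, `>= 2` distinct values).
#' @param metric `"euclidean"` or `"cosine"`.
#' @return a `cluster_report`: per-point `s`, the mean silhouette, per-cluster
#'   means, and the metric.
#' @export
silhouette_eval <- function(points, labels, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (nrow(points) != length(labels))
    stop_usage("points and labels length mismatch")
  ulab <- unique(labels)
  if (length(ulab) < 2L) stop_usage("silhouette requires >= 2 clusters")
  D <- pairwise_dist(points, metric)
  if (max(D) == 0)
    stop_usage("degenerate input: all points coincide")
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(ulab[ulab != labels[i]], function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  structure(list(s = s, mean = mean(s),
                 cluster_means = tapply(s, labels, mean),
                 metric = metric, labels = labels),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("silhouette (%s): mean %.4f over %d points, %d clusters\n",
              x$metric, x$mean, length(x$s), length(unique(x$labels))))
  invisible(x)
}

#' Clustering evaluation of sequence embeddings
#'
#' Embeds every sequence with the frozen encoder under length-adaptive
#' tokenization, then scores how well the embeddings separate the given
#' label classes with the silhouette coefficient. Optionally also scores a
#' seeded 2-D reduction (classical multidimensional scaling of the chosen
#' distance matrix) alongside the raw embedding space, since low-dimensional
#' projections can change silhouette values substantially.
#'
#' @param encoder an `rna_encoder`.
#' @param sequences character vector of normalized sequences.
#' @param labels class labels (`>= 2` classes).
#' @param bpe_model the `bpe_model` used for adaptive tokenization.
#' @param policy an [adaptive_policy()].
#' @param pooling `"mean"` or `"cls"` (see [embed_sequence()]).
#' @param metric `"euclidean"` or `"cosine"`.
#' @param reduce_2d also compute the silhouette on 2-D reduced coordinates.
#' @param seed seed (the reduction and any downstream stochastic step draw
#'   from it).
#' @return a `cluster_report` for the raw embeddings, with an additional
#'   `reduced` element when `reduce_2d = TRUE`.
#' @export
cluster_eval <- function(encoder, sequences, labels, bpe_model,
                         policy = adaptive_policy(), pooling = "mean",
                         metric = "euclidean", reduce_2d = FALSE, seed = 0L) {
  if (length(unique(labels)) < 2L) stop_usage(">= 2 label classes required")
  emb <- t(vapply(sequences, function(s)
    embed_sequence(encoder, adaptive_encode(bpe_model, policy, s), pooling),
    numeric(encoder$config$d)))
  rep_raw <- silhouette_eval(emb, labels, metric)
  if (reduce_2d) {
    red <- with_seed(seed, {
      D <- pairwise_dist(emb, metric)
      cmdscale(as.dist(D), k = 2L)
    })
    rep_raw$reduced <- silhouette_eval(red, labels, "euclidean")
  }
  rep_raw$embeddings <- emb
  rep_raw
}
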