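# Information-theoretic tokenization analysis: character entropy, exponential
# rank-frequency decay fits, closed-form and empirical token entropy, mean
# token length, and the per-character NUC/BPE entropy ratio.

#' Shannon entropy of a character distribution
#'
#' `-sum p log2 p` with the convention `0 * log 0 = 0`. Frequencies summing
#' to 1 within 0.001 (for instance, printed 4-decimal tables) are
#' renormalized on ingest and the deviation recorded as an attribute.
#'
#' @param freqs nonnegative probability vector.
#' @return entropy in bits per character, with attribute
#'   `renormalization_deviation`.
#' @export
char_entropy <- function(freqs) {
  if (any(freqs < 0)) stop_usage("frequencies must be nonnegative")
  dev <- sum(freqs) - 1
  if (abs(dev) > 1e-3)
    stop_usage("frequencies must sum to 1 (deviation ", signif(dev, 3), ")")
  p <- freqs / sum(freqs)
  p <- p[p > 0]
  structure(-sum(p * log2(p)), renormalization_deviation = dev)
}

#' Rank-frequency distribution of token counts
#'
#' @param token_counts named numeric vector (or token -> count list) of
#'   nonnegative counts with positive total.
#' @return data frame `(rank, token, probability)` in descending probability
#'   order, 1-based ranks, ties broken lexicographically on the token string.
#' @export
rank_frequency <- function(token_counts) {
  counts <- unlist(token_counts)
  if (length(counts) == 0L || sum(counts) <= 0)
    stop_usage("token_counts must be non-empty with positive total")
  ord <- order(-counts, names(counts), method = "radix")
  data.frame(rank = seq_along(counts),
             token = names(counts)[ord],
             probability = as.numeric(counts[ord] / sum(counts)),
             stringsAsFactors = FALSE)
}

#' Fit an exponential decay to a rank-frequency distribution
#'
#' Least-squares fit of `log2 p_i = log2 C - a * i` over 1-based ranks `i`,
#' modeling token probability as `P(x_i) = C / 2^(a i)`. Ranks with zero
#' probability are excluded from the regression.
#'
#' @param rank_dist data frame from [rank_frequency()] (columns `rank`,
#'   `probability`).
#' @return a `decay_fit`: `C`, `a`, the regression `r_squared`, `rank_origin
#'   = 1`, and `warn_nondecaying = TRUE` when the fitted `a <= 0`.
#' @export
fit_exponential_decay <- function(rank_dist) {
  keep <- rank_dist$probability > 0
  if (sum(keep) < 3L) stop_usage("need >= 3 ranks with positive probability")
  r <- rank_dist$rank[keep]
  y <- log2(rank_dist$probability[keep])
  fit <- lm(y ~ r)
  a <- -unname(coef(fit)[2L])
  C <- 2^unname(coef(fit)[1L])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(C = C, a = a,
                 r_squared = r2,
                 rank_origin = 1L,
                 warn_nondecaying = a <= 0),
            class = "decay_fit")
}

#' Closed-form token entropy of an exponential rank-frequency law
#'
#' Evaluates `log2((C + 1)^((C + 1)/C) / C)`, the closed-form entropy of a
#' geometric rank-frequency distribution with scale `C`. At `C = 1` this is
#' exactly 2 bits.
#'
#' @param C positive scale parameter of the decay law.
#' @return entropy in bits per token.
#' @export
closed_form_bpe_entropy <- function(C) {
  if (C <= 0) stop_usage("C must be positive")
  ((C + 1) / C) * log2(C + 1) - log2(C)
}

#' Empirical token entropy of a rank-frequency distribution
#'
#' @inheritParams fit_exponential_decay
#' @return `-sum p log2 p` in bits per token.
#' @export
empirical_token_entropy <- function(rank_dist) {
  p <- rank_dist$probability
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-character entropy and NUC/BPE entropy ratio
#'
#' Divides a per-token entropy by the mean token length to obtain bits per
#' character, and compares with the nucleotide-level entropy. A ratio below 1
#' quantifies the per-character information given up by subword compression.
#'
#' @param H_bpe token entropy in bits per token.
#' @param mean_len mean token length in characters per token (`> 0`).
#' @param H_nuc nucleotide entropy in bits per character (`> 0`).
#' @return list `(per_char, ratio)`, computed with unrounded intermediates.
#' @export
per_char_ratio <- function(H_bpe, mean_len, H_nuc) {
  if (mean_len <= 0 || H_nuc <= 0)
    stop_usage("mean_len and H_nuc must be positive")
  per_char <- H_bpe / mean_len
  list(per_char = per_char, ratio = per_char / H_nuc)
}

#' End-to-end tokenization entropy report
#'
#' Computes observed character frequencies and their entropy, tokenizes the
#' corpus with the trained BPE model, builds the token rank-frequency
#' distribution, fits the exponential decay law, and reports empirical and
#' closed-form token entropies, the observed mean token length, and the
#' per-character quantities. The ratio uses the empirical token entropy by
#' default; set `use_closed_form = TRUE` to use the closed-form value from
#' the fitted `C` instead (both are always reported).
#'
#' @param corpus character vector of normalized sequences.
#' @param bpe_model a trained `bpe_model`.
#' @param use_closed_form use the closed-form entropy in the ratio.
#' @return an `entropy_report`.
#' @export
build_entropy_report <- function(corpus, bpe_model, use_closed_form = FALSE) {
  if (length(corpus) == 0L) stop_usage("corpus must be non-empty")
  all_chars <- strsplit(paste(corpus, collapse = ""), "", fixed = TRUE)[[1]]
  base_counts <- table(factor(all_chars, levels = c("A", "C", "G", "U")))
  char_freqs <- as.numeric(base_counts) / sum(base_counts)
  names(char_freqs) <- c("A", "C", "G", "U")
  H_nuc <- as.numeric(char_entropy(char_freqs))

  tok_lists <- lapply(corpus, function(s) encode_bpe(bpe_model, s)$ids)
  ids <- unlist(tok_lists)
  counts <- table(ids)
  names(counts) <- bpe_model$vocab$tokens[as.integer(names(counts))]
  rank_dist <- rank_frequency(as.numeric(counts) |> setNames(names(counts)))

  mean_len <- sum(nchar(corpus)) / length(ids)
  H_emp <- empirical_token_entropy(rank_dist)
  fit <- if (nrow(rank_dist) >= 3L) fit_exponential_decay(rank_dist) else NULL
  H_closed <- if (!is.null(fit) && fit$C > 0) closed_form_bpe_entropy(fit$C) else NA_real_
  H_used <- if (use_closed_form) H_closed else H_emp
  pcr <- per_char_ratio(H_used, mean_len, H_nuc)

  structure(list(char_freqs = char_freqs,
                 H_nuc = H_nuc,
                 rank_dist = rank_dist,
                 decay_fit = fit,
                 H_bpe_empirical = H_emp,
                 H_bpe_closed_form = H_closed,
                 mean_token_length = mean_len,
                 per_char = pcr$per_char,
                 ratio = pcr$ratio,
                 entropy_basis = if (use_closed_form) "closed_form" else "empirical"),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("entropy report: H_NUC %.4f bits/char; H_BPE %.4f bits/token (closed form %.4f);\n",
              x$H_nuc, x$H_bpe_empirical, x$H_bpe_closed_form))
  cat(sprintf("  mean token length %.4f; per-char %.4f bits; ratio %.4f (%s basis)\n",
              x$mean_token_length, x$per_char, x$ratio, x$entropy_basis))
  invisible(x)
}
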