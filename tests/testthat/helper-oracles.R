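# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# non-overlapping adjacent-pair counts over a list of token-string vectors
oracle_pair_counts <- function(seq_tokens) {
  counts <- list()
  for (toks in seq_tokens) {
    n <- length(toks)
    if (n < 2) next
    pairs <- paste(toks[-n], toks[-1], sep = "\r")
    for (pr in unique(pairs)) {
      idx <- which(pairs == pr)
      cnt <- 0L
      last <- -1L
      for (i in idx) {
        if (i > last) {
          cnt <- cnt + 1L
          last <- i + 1L
        }
      }
      counts[[pr]] <- (counts[[pr]] %||% 0L) + cnt
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy left-to-right replacement of the pair (a, b) by the merged string
oracle_replace <- function(toks, a, b) {
  out <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    if (i < n && toks[i] == a && toks[i + 1] == b) {
      out <- c(out, paste0(a, b))
      i <- i + 2L
    } else {
      out <- c(out, toks[i])
      i <- i + 1L
    }
  }
  out
}

# full greedy BPE trainer oracle: recounts all pairs from scratch each
# iteration; lexicographic tie-break on the concatenated string; stops when
# no pair occurs at least twice. Returns the ordered merge list as strings.
oracle_bpe_train <- function(corpus, max_merges) {
  seq_tokens <- lapply(strsplit(corpus, "", fixed = TRUE), identity)
  merges <- character(0)
  for (k in seq_len(max_merges)) {
    counts <- oracle_pair_counts(seq_tokens)
    if (length(counts) == 0) break
    concat <- gsub("\r", "", names(counts), fixed = TRUE)
    cnt <- unlist(counts)
    best <- max(cnt)
    if (best < 2) break
    cand <- which(cnt == best)
    pick <- cand[order(concat[cand])][1]
    ab <- strsplit(names(counts)[pick], "\r", fixed = TRUE)[[1]]
    merges <- c(merges, concat[pick])
    seq_tokens <- lapply(seq_tokens, oracle_replace, a = ab[1], b = ab[2])
  }
  merges
}

# brute-force silhouette of labeled points (euclidean)
oracle_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  D <- as.matrix(dist(points))
  labels <- as.character(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(D[i, same])
    bs <- sapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]))
    b <- min(bs)
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_seq <- function(L, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}
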