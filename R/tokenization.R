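# Tokenization: shared vocabulary, BPE training/encoding, single-nucleotide
# (NUC) encoding, length-adaptive dispatch, and plain-text model persistence.

.SPECIALS <- c("[PAD]", "[MASK]", "[CLS]", "[SEP]", "[UNK]")
.BASES <- c("A", "C", "G", "U")

#' Construct a token vocabulary
#'
#' A single vocabulary is shared by both tokenization schemes: five special
#' tokens (`[PAD]`, `[MASK]`, `[CLS]`, `[SEP]`, `[UNK]`) occupy the reserved
#' low identifiers 1--5, the four RNA bases occupy 6--9, and learned BPE merge
#' tokens follow. NUC tokenization uses only the base subset; ambiguity
#' symbols (`N` and anything else outside the alphabet) map to `[UNK]`.
#'
#' @param merge_tokens character vector of multi-character merged token
#'   strings, in merge order.
#' @return an object of class `rna_vocabulary`.
#' @export
new_vocabulary <- function(merge_tokens = character()) {
  tokens <- c(.SPECIALS, .BASES, merge_tokens)
  if (anyDuplicated(tokens))
    stop_usage("vocabulary token strings must be unique")
  structure(
    list(tokens = tokens,
         n_special = length(.SPECIALS),
         base_ids = seq_along(.BASES) + length(.SPECIALS)),
    class = "rna_vocabulary")
}

#' @export
length.rna_vocabulary <- function(x) length(x$tokens)

#' Look up token identifiers by token string
#' @param vocab an `rna_vocabulary`.
#' @param tok character vector of token strings.
#' @return integer identifiers (`NA` for unknown strings).
#' @export
vocab_id <- function(vocab, tok) match(tok, vocab$tokens)

special_ids <- function(vocab) seq_len(vocab$n_special)
mask_id <- function(vocab) 2L
unk_id <- function(vocab) 5L
cls_id <- function(vocab) 3L

# fast character -> id lookup table indexed by byte value
char_id_table <- function(vocab) {
  tab <- rep(unk_id(vocab), 256L)
  for (i in seq_along(.BASES)) tab[utf8ToInt(.BASES[i])] <- vocab$base_ids[i]
  tab
}

chars_to_ids <- function(seq, tab) {
  if (nchar(seq) == 0L) return(integer(0))
  tab[utf8ToInt(seq)]
}

#' Train a byte-pair-encoding tokenizer on an RNA corpus
#'
#' Greedy BPE: each iteration counts adjacent token pairs over the whole
#' corpus (left-to-right and non-overlapping within a sequence, so `"AAA"`
#' contains one `"AA"`), merges every occurrence of the most frequent pair,
#' adds the concatenation to the vocabulary, and repeats until the vocabulary
#' reaches `target_vocab_size` or no pair occurs at least twice. Ties between
#' equally frequent pairs are broken lexicographically on the concatenated
#' token string. Merges never involve special tokens or the ambiguity symbol,
#' so no learned token spans an `N`.
#'
#' @param corpus character vector of normalized RNA sequences.
#' @param target_vocab_size total vocabulary size including the five special
#'   and four base tokens (the full-scale default in this framework is 4096).
#' @return an object of class `bpe_model` holding the ordered merge list, the
#'   shared vocabulary and training metadata.
#' @seealso [encode_bpe()], [save_bpe_model()]
#' @export
train_bpe <- function(corpus, target_vocab_size = 4096L) {
  if (length(corpus) == 0L) stop_usage("corpus must be non-empty")
  base_vocab <- new_vocabulary()
  if (target_vocab_size < length(base_vocab))
    stop_usage("target_vocab_size must be at least the base vocabulary size (",
               length(base_vocab), ")")
  tab <- char_id_table(base_vocab)
  seqs <- lapply(corpus, chars_to_ids, tab = tab)
  max_new <- target_vocab_size - length(base_vocab)
  fit <- cpp_bpe_train(seqs, base_vocab$tokens, as.integer(max_new), 2L,
                       base_vocab$n_special)
  vocab <- new_vocabulary(fit$new_tokens)
  merges <- fit$merges
  storage.mode(merges) <- "integer"
  structure(
    list(merges = merges,
         merged_ids = seq_len(nrow(merges)) + length(base_vocab),
         vocab = vocab,
         target_vocab_size = as.integer(target_vocab_size),
         corpus_sequences = length(corpus),
         corpus_nt = sum(nchar(corpus))),
    class = "bpe_model")
}

#' @export
print.bpe_model <- function(x, ...) {
  cat("BPE model:", nrow(x$merges), "merges, vocabulary size",
      length(x$vocab), "\n")
  invisible(x)
}

new_token_seq <- function(scheme, ids, source_length) {
  structure(list(scheme = scheme, ids = as.integer(ids),
                 source_length = as.integer(source_length)),
            class = "token_seq")
}

#' Tokenize a sequence with a trained BPE model
#'
#' Applies the recorded merges in learned order. Characters outside the
#' alphabet become `[UNK]` and are never merged.
#'
#' @param model a `bpe_model`.
#' @param sequence a single normalized RNA string.
#' @return a `token_seq` with scheme `"BPE"`; its token count never exceeds
#'   the nucleotide count.
#' @export
encode_bpe <- function(model, sequence) {
  stopifnot(inherits(model, "bpe_model"), length(sequence) == 1L)
  tab <- char_id_table(model$vocab)
  ids <- chars_to_ids(sequence, tab)
  if (length(ids) > 1L && nrow(model$merges) > 0L)
    ids <- cpp_apply_merges(ids, model$merges, model$merged_ids)
  new_token_seq("BPE", ids, nchar(sequence))
}

#' Tokenize a sequence at single-nucleotide resolution
#'
#' @param vocab an `rna_vocabulary`.
#' @param sequence a single normalized RNA string.
#' @return a `token_seq` with scheme `"NUC"` and exactly one token per
#'   nucleotide.
#' @export
encode_nuc <- function(vocab, sequence) {
  stopifnot(inherits(vocab, "rna_vocabulary"), length(sequence) == 1L)
  ids <- chars_to_ids(sequence, char_id_table(vocab))
  new_token_seq("NUC", ids, nchar(sequence))
}

#' Decode token identifiers back to a nucleotide string
#'
#' Special tokens `[PAD]`, `[CLS]`, `[SEP]` are dropped, `[UNK]` decodes to
#' the ambiguity symbol `N`, and `[MASK]` decodes to the glyph `?` since the
#' original nucleotides are unrecoverable at masked positions.
#'
#' @param vocab an `rna_vocabulary`.
#' @param token_seq a `token_seq` (or bare integer id vector).
#' @return a single character string.
#' @export
decode <- function(vocab, token_seq) {
  ids <- if (inherits(token_seq, "token_seq")) token_seq$ids else as.integer(token_seq)
  if (length(ids) == 0L) return("")
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > length(vocab)))
    stop_usage("token identifier outside vocabulary")
  out <- vocab$tokens[ids]
  out[ids == mask_id(vocab)] <- "?"
  out[ids == unk_id(vocab)] <- "N"
  out[ids %in% c(1L, 3L, 4L)] <- ""
  paste(out, collapse = "")
}

#' Length-adaptive tokenization policy
#'
#' Sequences at or below the threshold are tokenized at nucleotide resolution
#' (full fidelity); longer sequences fall back to BPE so that compressed token
#' counts stay within a fixed compute/memory budget.
#'
#' @param threshold length threshold in nucleotides; the boundary length
#'   itself counts as short. Default 1024, a typical encoder context window.
#' @return an `adaptive_policy`.
#' @export
adaptive_policy <- function(threshold = 1024L) {
  if (threshold < 1L) stop_usage("threshold must be >= 1")
  structure(list(threshold = as.integer(threshold)), class = "adaptive_policy")
}

#' Tokenize with length-based dispatch between NUC and BPE
#'
#' @param model a `bpe_model`.
#' @param policy an [adaptive_policy()].
#' @param sequence a single normalized RNA string.
#' @return a `token_seq` whose `scheme` tag records the choice.
#' @export
adaptive_encode <- function(model, policy, sequence) {
  stopifnot(inherits(policy, "adaptive_policy"))
  if (nchar(sequence) <= policy$threshold)
    encode_nuc(model$vocab, sequence)
  else
    encode_bpe(model, sequence)
}

#' Save / load a BPE model as plain text
#'
#' The file holds a schema header, the vocabulary as `token<TAB>id` lines and
#' one merge pair (token strings, tab-separated) per line in learned order.
#'
#' @param model a `bpe_model`.
#' @param path file path.
#' @return `load_bpe_model` returns a `bpe_model` identical to the one saved.
#' @export
save_bpe_model <- function(model, path) {
  stopifnot(inherits(model, "bpe_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("rnalm-bpe\t1",
               "alphabet\tACGUN",
               paste0("vocab_size\t", length(model$vocab)),
               paste0("corpus_sequences\t", model$corpus_sequences),
               paste0("corpus_nt\t", model$corpus_nt),
               "[VOCAB]"), con)
  writeLines(paste0(model$vocab$tokens, "\t", seq_along(model$vocab$tokens)), con)
  writeLines("[MERGES]", con)
  if (nrow(model$merges) > 0L) {
    left <- model$vocab$tokens[model$merges[, 1L]]
    right <- model$vocab$tokens[model$merges[, 2L]]
    writeLines(paste0(left, "\t", right), con)
  }
  invisible(path)
}

#' @rdname save_bpe_model
#' @export
load_bpe_model <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: ", path)
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != 2L || hdr[1L] != "rnalm-bpe" || hdr[2L] != "1")
    stop_usage("unrecognized BPE model schema in ", path)
  iv <- which(lines == "[VOCAB]")
  im <- which(lines == "[MERGES]")
  if (length(iv) != 1L || length(im) != 1L || im <= iv)
    stop_usage("corrupted BPE model file: missing sections")
  meta <- strsplit(lines[2:(iv - 1L)], "\t", fixed = TRUE)
  meta <- setNames(vapply(meta, `[`, character(1), 2L),
                   vapply(meta, `[`, character(1), 1L))
  vocab_lines <- strsplit(lines[(iv + 1L):(im - 1L)], "\t", fixed = TRUE)
  toks <- vapply(vocab_lines, `[`, character(1), 1L)
  ids <- as.integer(vapply(vocab_lines, `[`, character(1), 2L))
  toks <- toks[order(ids)]
  n_fixed <- length(.SPECIALS) + length(.BASES)
  if (!identical(toks[seq_len(n_fixed)], c(.SPECIALS, .BASES)))
    stop_usage("corrupted BPE model file: unexpected base vocabulary")
  vocab <- new_vocabulary(toks[-seq_len(n_fixed)])
  merge_lines <- if (im < length(lines)) lines[(im + 1L):length(lines)] else character()
  merge_lines <- merge_lines[nzchar(merge_lines)]
  if (length(merge_lines) > 0L) {
    ml <- strsplit(merge_lines, "\t", fixed = TRUE)
    merges <- cbind(vocab_id(vocab, vapply(ml, `[`, character(1), 1L)),
                    vocab_id(vocab, vapply(ml, `[`, character(1), 2L)))
    if (anyNA(merges)) stop_usage("corrupted BPE model file: unknown merge token")
  } else {
    merges <- matrix(integer(0), 0L, 2L)
  }
  storage.mode(merges) <- "integer"
  structure(
    list(merges = merges,
         merged_ids = seq_len(nrow(merges)) + n_fixed,
         vocab = vocab,
         target_vocab_size = as.integer(meta[["vocab_size"]]),
         corpus_sequences = as.integer(meta[["corpus_sequences"]]),
         corpus_nt = as.numeric(meta[["corpus_nt"]])),
    class = "bpe_model")
}

#' Mean token length of a model on a set of sequences
#'
#' Nucleotides per BPE token, the compression factor realized by the trained
#' merges (about 6.1 at full scale on natural non-coding RNA).
#'
#' @param model a `bpe_model`.
#' @param sequences character vector of normalized sequences.
#' @return mean characters per token (a number `>= 1`).
#' @export
mean_token_length <- function(model, sequences) {
  ntok <- vapply(sequences, function(s) length(encode_bpe(model, s)$ids),
                 numeric(1))
  sum(nchar(sequences)) / sum(ntok)
}
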