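# Sequence I/O, normalization, and seeded synthetic corpora / task fixtures.
# A corpus is represented as a named character vector: names are record
# identifiers, values are normalized RNA sequences.

#' Read an RNA FASTA file
#'
#' Multi-line (wrapped) sequences are concatenated; record order is
#' preserved. An empty file yields an empty corpus.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: ", path)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L)) {
    bad <- names(seqs)[which(nchar(seqs) == 0L)[1L]]
    stop_usage("record with empty sequence: ", bad)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param wrap line width for sequence wrapping (positive integer).
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (wrap < 1L) stop_usage("wrap must be a positive integer")
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(wrap))
  invisible(path)
}

#' Normalize raw sequence strings to the RNA alphabet
#'
#' Uppercases and maps T to U (DNA input is accepted and unified to RNA).
#' Characters outside `{A, C, G, U}` are handled by `policy`: `"reject"`
#' raises an error naming the first offending position, `"replace"` turns
#' them into the ambiguity symbol `N`, and `"drop"` removes them.
#' Normalization is idempotent.
#'
#' @param raw character vector of raw sequences.
#' @param policy one of `"reject"`, `"replace"`, `"drop"`.
#' @return character vector of normalized sequences, with attribute
#'   `n_ambiguous` (count of replaced characters) when `policy = "replace"`.
#' @export
normalize_sequence <- function(raw, policy = c("reject", "replace", "drop")) {
  policy <- match.arg(policy)
  x <- chartr("t", "u", toupper(raw))
  x <- chartr("T", "U", x)
  foreign <- gsub("[ACGU]", "", x)
  if (policy == "reject") {
    bad <- which(nchar(foreign) > 0L)
    if (length(bad) > 0L) {
      i <- bad[1L]
      pos <- regexpr("[^ACGU]", x[i])
      stop_usage("foreign character '", substr(x[i], pos, pos),
                 "' at position ", pos, " of sequence ", i)
    }
    return(x)
  }
  if (policy == "replace") {
    out <- gsub("[^ACGU]", "N", x)
    attr(out, "n_ambiguous") <- sum(nchar(foreign))
    return(out)
  }
  gsub("[^ACGU]", "", x)
}

#' Nucleotide frequencies observed in large non-coding RNA collections
#'
#' The default background composition used by the synthetic corpus generator:
#' A 0.2726, C 0.2664, G 0.2465, U 0.2144 (renormalized; the printed values
#' sum to 0.9999).
#'
#' @return named numeric vector over `c(A, C, G, U)` summing to 1.
#' @export
rna_base_frequencies <- function() {
  p <- c(A = 0.2726, C = 0.2664, G = 0.2465, U = 0.2144)
  p / sum(p)
}

#' Length models for synthetic corpora
#'
#' `length_fixed` gives every sequence the same length; `length_uniform`
#' draws uniformly on `[lo, hi]`; `length_geom` draws a geometric
#' (exponential-tail) length with the given mean, truncated at `max` --
#' emulating the heavy right tail of natural ncRNA length distributions.
#'
#' @param n,lo,hi,mean,max positive integers.
#' @return a length-model object used by [corpus_spec()].
#' @export
length_fixed <- function(n) {
  stopifnot(n >= 1)
  structure(list(kind = "fixed", n = as.integer(n), max = as.integer(n)),
            class = "length_model")
}

#' @rdname length_fixed
#' @export
length_uniform <- function(lo, hi) {
  if (lo > hi) stop_usage("lo must be <= hi")
  structure(list(kind = "uniform", lo = as.integer(lo), hi = as.integer(hi),
                 max = as.integer(hi)), class = "length_model")
}

#' @rdname length_fixed
#' @export
length_geom <- function(mean, max = 10000L) {
  stopifnot(mean >= 1, max >= 1)
  structure(list(kind = "geom", mean = mean, max = as.integer(max)),
            class = "length_model")
}

#' Specification of a synthetic RNA corpus
#'
#' @param n_sequences number of records.
#' @param base_frequencies probability vector over `c(A, C, G, U)`; must be
#'   nonnegative and sum to 1 within 1e-9.
#' @param length_model a [length_fixed()], [length_uniform()] or
#'   [length_geom()] object.
#' @param motif_set list of `list(motif = <string>, prob = <number>)`. Under
#'   `motif_mode = "insert"` each motif is planted (overwriting the
#'   background) at a uniform random position with probability `prob`,
#'   independently per record. Under `motif_mode = "tile"` each record is a
#'   concatenation of motifs drawn with weights `prob`, separated by short
#'   background spacers, truncated to the sampled length -- emulating the
#'   dense repeat/domain structure of natural ncRNA families.
#' @param motif_mode `"insert"` or `"tile"` (ignored when `motif_set` is
#'   empty).
#' @param spacer_range integer range (lo, hi) of background spacer lengths
#'   between tiled motifs.
#' @param seed integer seed; corpus generation is a pure function of the
#'   spec, seed included.
#' @return a `corpus_spec`.
#' @export
corpus_spec <- function(n_sequences,
                        base_frequencies = rna_base_frequencies(),
                        length_model = length_geom(300),
                        motif_set = list(),
                        motif_mode = c("insert", "tile"),
                        spacer_range = c(0L, 2L),
                        seed = 0L) {
  motif_mode <- match.arg(motif_mode)
  if (n_sequences < 0) stop_usage("n_sequences must be nonnegative")
  if (length(base_frequencies) != 4L || any(base_frequencies < 0))
    stop_usage("base_frequencies must be 4 nonnegative values")
  if (abs(sum(base_frequencies) - 1) > 1e-9)
    stop_usage("base_frequencies must sum to 1")
  if (!inherits(length_model, "length_model"))
    stop_usage("length_model must be a length-model object")
  for (m in motif_set) {
    if (grepl("[^ACGU]", m$motif))
      stop_usage("motif contains characters outside the RNA alphabet: ", m$motif)
    if (nchar(m$motif) > length_model$max)
      stop_usage("degenerate length model: maximum length ", length_model$max,
                 " is shorter than motif ", m$motif)
  }
  if (motif_mode == "tile" && length(motif_set) == 0L)
    stop_usage("tile mode requires a non-empty motif_set")
  structure(list(n_sequences = as.integer(n_sequences),
                 base_frequencies = setNames(as.numeric(base_frequencies),
                                             c("A", "C", "G", "U")),
                 length_model = length_model,
                 motif_set = motif_set,
                 motif_mode = motif_mode,
                 spacer_range = as.integer(spacer_range),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

sample_lengths <- function(lm, n) {
  switch(lm$kind,
         fixed = rep(lm$n, n),
         uniform = sample(lm$lo:lm$hi, n, replace = TRUE),
         geom = pmax(1L, pmin(lm$max, 1L + rgeom(n, prob = 1 / lm$mean))))
}

#' Generate a seeded synthetic RNA corpus
#'
#' Background nucleotides are drawn i.i.d. from the spec's base frequencies;
#' motifs are then planted per the spec. Deterministic given the spec.
#'
#' @param spec a [corpus_spec()].
#' @return named character vector of sequences.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(spec$seed, {
    n <- spec$n_sequences
    if (n == 0L) return(setNames(character(0), character(0)))
    lens <- sample_lengths(spec$length_model, n)
    mode <- spec$motif_mode %||% "insert"
    if (mode == "tile" && length(spec$motif_set) > 0L) {
      motifs <- vapply(spec$motif_set, `[[`, character(1), "motif")
      weights <- vapply(spec$motif_set, `[[`, numeric(1), "prob")
      sp <- spec$spacer_range
      seqs <- vapply(lens, function(L) {
        parts <- character(0)
        total <- 0L
        while (total < L) {
          k <- sample(sp[1]:sp[2], 1L)
          spacer <- if (k > 0) paste(sample(c("A", "C", "G", "U"), k,
                                           replace = TRUE,
                                           prob = spec$base_frequencies),
                                     collapse = "") else ""
          m <- motifs[sample.int(length(motifs), 1L, prob = weights)]
          parts <- c(parts, spacer, m)
          total <- total + k + nchar(m)
        }
        substr(paste(parts, collapse = ""), 1L, L)
      }, character(1))
    } else {
      seqs <- vapply(lens, function(L) {
        paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                     prob = spec$base_frequencies), collapse = "")
      }, character(1))
      for (i in seq_len(n)) {
        for (m in spec$motif_set) {
          w <- nchar(m$motif)
          if (w <= lens[i] && runif(1) < m$prob) {
            pos <- sample.int(lens[i] - w + 1L, 1L)
            substr(seqs[i], pos, pos + w - 1L) <- m$motif
          }
        }
      }
    }
    setNames(seqs, sprintf("synth_%06d", seq_len(n)))
  })
}

#' Motif set planted in the default pretraining corpus
#'
#' Six fixed 12-mers, each inserted with probability 1, covering roughly half
#' of a 120-nt sequence. They give the masked-LM objective recoverable local
#' structure: a model that identifies which motif surrounds a masked position
#' can recover the masked nucleotide exactly, whereas background positions
#' are irreducibly uncertain.
#'
#' @return list of `list(motif, prob)` entries.
#' @export
default_motif_set <- function() {
  motifs <- c("GGACUAGCGGAU", "CCUAGGUUACGC", "AGGCAAUGGCAU",
              "UUCGACGGAUCC", "CAGUUCAGGAUA", "GCGUAAACCGUU")
  lapply(motifs, function(m) list(motif = m, prob = 1.0))
}

#' Canonical corpus specification for desk-scale dual pretraining
#'
#' The study conditions used by the package's own pretraining demonstrations
#' and tests: 120-nt sequences tiled from four fixed 12-nt motifs separated
#' by 0--2 background nucleotides. The tiling gives the masked-LM objective
#' a strong, local, recoverable signal -- inside a motif the masked base is
#' determined by its neighbors -- while the spacers and truncation keep the
#' task nontrivial; a model that ignores context cannot beat the base
#' composition floor of about 2 bits.
#'
#' @param n_sequences number of records.
#' @param seed integer seed.
#' @return a [corpus_spec()] in tile mode.
#' @export
pretrain_corpus_spec <- function(n_sequences, seed = 0L) {
  corpus_spec(n_sequences,
              length_model = length_fixed(120),
              motif_set = default_motif_set()[1:4],
              motif_mode = "tile",
              spacer_range = c(0L, 2L),
              seed = seed)
}

# ---- downstream-task fixtures ------------------------------------------------

random_rna <- function(L, freqs = rna_base_frequencies()) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE, prob = freqs),
        collapse = "")
}

# single well-nested hairpin over a sequence of length L:
# flank | 5' stem | loop | 3' stem | flank, with complementary stem bases
sample_hairpin <- function(L) {
  stem <- sample(5:8, 1L)
  loop <- sample(3:6, 1L)
  while (2L * stem + loop + 2L > L) stem <- stem - 1L
  room <- L - (2L * stem + loop)
  f1 <- sample.int(room + 1L, 1L) - 1L
  seq <- strsplit(random_rna(L), "", fixed = TRUE)[[1]]
  i5 <- f1 + seq_len(stem)
  i3 <- f1 + stem + loop + seq_len(stem)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seq[i3] <- comp[seq[rev(i5)]]
  pairs <- cbind(i5, rev(i3))
  M <- matrix(0L, L, L)
  M[pairs] <- 1L
  M[pairs[, c(2, 1), drop = FALSE]] <- 1L
  list(sequence = paste(seq, collapse = ""), pairing = M, pairs = pairs)
}

# deterministic 3-D walk over a hairpin structure: stem positions advance
# along a helix, loop/flank positions turn by base-keyed angles in the plane.
# A synthetic stand-in for backbone geometry, not a physical model.
structure_coords <- function(sequence, pairing) {
  L <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paired <- rowSums(pairing) > 0
  turn <- c(A = 40, C = -40, G = 100, U = -100) * pi / 180
  xyz <- matrix(0, L, 3)
  ang <- 0
  z <- 0
  pos <- c(0, 0, 0)
  for (i in seq_len(L)) {
    if (paired[i]) {
      ang <- ang + 32.7 * pi / 180
      z <- z + 2.8
      pos <- c(9 * cos(ang), 9 * sin(ang), z)
    } else {
      ang <- ang + turn[ch[i]]
      pos <- pos + c(5.9 * cos(ang), 5.9 * sin(ang), 1.0)
    }
    xyz[i, ] <- pos
  }
  xyz
}

# fixed per-dinucleotide torsion table in degrees, deterministic
torsion_table <- function() {
  dinucs <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                            paste0))
  angles <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  tab <- matrix(0, length(dinucs), length(angles),
                dimnames = list(dinucs, angles))
  for (i in seq_along(dinucs))
    for (j in seq_along(angles))
      tab[i, j] <- ((i * 47 + j * 101) %% 360) - 179
  tab
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Generate a downstream-task fixture with planted, recoverable signal
#'
#' Task fixtures emulate the shapes of real downstream datasets while keeping
#' the labels a known function of the sequences:
#' \describe{
#'   \item{pair_interaction}{pairs of (short, long) sequences; the label is 1
#'     exactly when the short sequence carries a fixed motif and the long one
#'     carries its reverse complement. A Bayes-optimal rule on the planted
#'     motif attains near-perfect accuracy.}
#'   \item{seq_classification}{fixed-width windows labeled by which
#'     class-specific motif was planted.}
#'   \item{pairing_map}{sequences folded into a single well-nested hairpin;
#'     the label is the symmetric binary base-pairing matrix with
#'     complementary bases forced at paired positions.}
#'   \item{distance_map}{the same hairpin structures with pairwise distances
#'     from a deterministic 3-D helical walk over the structure.}
#'   \item{torsion_angles}{seven backbone/base angles per position, each a
#'     fixed function of the local dinucleotide plus bounded uniform noise,
#'     encoded in degrees in (-180, 180].}
#' }
#'
#' @param kind one of the task kinds above.
#' @param n number of records (pairs, for `pair_interaction`).
#' @param seed integer seed.
#' @param len,len2 sequence length(s); defaults per kind.
#' @param noise_sd half-width in degrees of the uniform angle noise
#'   (`torsion_angles` only); zero makes angles an exact function of sequence.
#' @return a `task_fixture`: `list(kind, records, labels, meta)`.
#' @export
generate_task_fixture <- function(kind = c("pair_interaction",
                                           "seq_classification",
                                           "pairing_map", "distance_map",
                                           "torsion_angles"),
                                  n, seed = 0L, len = NULL, len2 = NULL,
                                  noise_sd = 10) {
  kind <- match.arg(kind)
  with_seed(seed, {
    switch(kind,
      pair_interaction = {
        len <- len %||% 24L
        len2 <- len2 %||% 80L
        motif <- "GGACUAGCGGAU"
        rc <- revcomp_rna(motif)
        lab <- rbinom(n, 1L, 0.5)
        s1 <- character(n)
        s2 <- character(n)
        for (i in seq_len(n)) {
          s1[i] <- random_rna(len)
          s2[i] <- random_rna(len2)
          if (lab[i] == 1L) {
            p1 <- sample.int(len - nchar(motif) + 1L, 1L)
            substr(s1[i], p1, p1 + nchar(motif) - 1L) <- motif
            p2 <- sample.int(len2 - nchar(rc) + 1L, 1L)
            substr(s2[i], p2, p2 + nchar(rc) - 1L) <- rc
          }
        }
        structure(list(kind = kind,
                       records = list(first = setNames(s1, sprintf("p%04d_a", 1:n)),
                                      second = setNames(s2, sprintf("p%04d_b", 1:n))),
                       labels = lab,
                       meta = list(motif = motif)),
                  class = "task_fixture")
      },
      seq_classification = {
        len <- len %||% 101L
        class_motifs <- c("GGAUCCGGAUCC", "AAUUCGCGAAUU")
        lab <- sample(seq_along(class_motifs), n, replace = TRUE)
        seqs <- vapply(seq_len(n), function(i) {
          s <- random_rna(len)
          m <- class_motifs[lab[i]]
          # planted twice so the class signal survives mean pooling
          for (k in 1:2) {
            p <- sample.int(len - nchar(m) + 1L, 1L)
            substr(s, p, p + nchar(m) - 1L) <- m
          }
          s
        }, character(1))
        structure(list(kind = kind,
                       records = setNames(seqs, sprintf("cls%04d", 1:n)),
                       labels = lab,
                       meta = list(class_motifs = class_motifs)),
                  class = "task_fixture")
      },
      pairing_map = {
        len <- len %||% 24L
        hp <- lapply(seq_len(n), function(i) sample_hairpin(len))
        structure(list(kind = kind,
                       records = setNames(vapply(hp, `[[`, character(1),
                                                 "sequence"),
                                          sprintf("ss%04d", 1:n)),
                       labels = lapply(hp, `[[`, "pairing"),
                       meta = list()),
                  class = "task_fixture")
      },
      distance_map = {
        len <- len %||% 24L
        hp <- lapply(seq_len(n), function(i) sample_hairpin(len))
        dm <- lapply(hp, function(h)
          as.matrix(dist(structure_coords(h$sequence, h$pairing))))
        structure(list(kind = kind,
                       records = setNames(vapply(hp, `[[`, character(1),
                                                 "sequence"),
                                          sprintf("dm%04d", 1:n)),
                       labels = dm,
                       meta = list()),
                  class = "task_fixture")
      },
      torsion_angles = {
        len <- len %||% 40L
        tab <- torsion_table()
        seqs <- vapply(seq_len(n), function(i) random_rna(len), character(1))
        labels <- lapply(seqs, function(s) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          di <- paste0(c(ch[1], ch[-length(ch)]), ch)
          base <- tab[di, , drop = FALSE]
          noise <- matrix(runif(length(base), -noise_sd, noise_sd),
                          nrow(base), ncol(base))
          ang <- wrap_angle(base + noise)
          dimnames(ang) <- NULL
          ang
        })
        structure(list(kind = kind,
                       records = setNames(seqs, sprintf("ta%04d", 1:n)),
                       labels = labels,
                       meta = list(noise_sd = noise_sd)),
                  class = "task_fixture")
      })
  })
}

# ---- fixture serialization ---------------------------------------------------

write_matrix_file <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("L", nrow(M)), con)
  write.table(format(M, digits = 8, scientific = FALSE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_file <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), " ", fixed = TRUE)[[1L]]
  if (hdr[1L] != "L") stop_usage("matrix file missing 'L <n>' header: ", path)
  n <- as.integer(hdr[2L])
  M <- as.matrix(read.table(path, skip = 1L, nrows = n))
  dimnames(M) <- NULL
  M
}

#' Serialize / load a task fixture
#'
#' Sequences are written as FASTA; labels as tab-separated text
#' (classification kinds), per-record whitespace matrix files with an
#' `L <n>` header (map kinds), or per-position angle tables (torsion).
#'
#' @param fixture a `task_fixture`.
#' @param dir output directory (created if needed).
#' @return `read_fixture` returns a `task_fixture`.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "task_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  k <- fixture$kind
  if (k == "pair_interaction") {
    write_fasta(fixture$records$first, file.path(dir, "first.fasta"))
    write_fasta(fixture$records$second, file.path(dir, "second.fasta"))
    write.table(data.frame(first = names(fixture$records$first),
                           second = names(fixture$records$second),
                           label = fixture$labels),
                file.path(dir, "labels.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (k == "seq_classification") {
    write_fasta(fixture$records, file.path(dir, "sequences.fasta"))
    write.table(data.frame(id = names(fixture$records),
                           class = fixture$labels),
                file.path(dir, "labels.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (k %in% c("pairing_map", "distance_map")) {
    write_fasta(fixture$records, file.path(dir, "sequences.fasta"))
    for (i in seq_along(fixture$labels))
      write_matrix_file(fixture$labels[[i]],
                        file.path(dir, paste0(names(fixture$records)[i], ".mat")))
  } else if (k == "torsion_angles") {
    write_fasta(fixture$records, file.path(dir, "sequences.fasta"))
    for (i in seq_along(fixture$labels)) {
      df <- as.data.frame(fixture$labels[[i]])
      colnames(df) <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                        "chi")
      write.table(df, file.path(dir, paste0(names(fixture$records)[i], ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  writeLines(k, file.path(dir, "kind.txt"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  kind <- readLines(file.path(dir, "kind.txt"), n = 1L)
  if (kind == "pair_interaction") {
    lab <- read.table(file.path(dir, "labels.tsv"), header = TRUE, sep = "\t")
    structure(list(kind = kind,
                   records = list(first = read_fasta(file.path(dir, "first.fasta")),
                                  second = read_fasta(file.path(dir, "second.fasta"))),
                   labels = lab$label, meta = list()),
              class = "task_fixture")
  } else if (kind == "seq_classification") {
    lab <- read.table(file.path(dir, "labels.tsv"), header = TRUE, sep = "\t")
    structure(list(kind = kind,
                   records = read_fasta(file.path(dir, "sequences.fasta")),
                   labels = lab$class, meta = list()),
              class = "task_fixture")
  } else if (kind %in% c("pairing_map", "distance_map")) {
    recs <- read_fasta(file.path(dir, "sequences.fasta"))
    labels <- lapply(names(recs), function(id)
      read_matrix_file(file.path(dir, paste0(id, ".mat"))))
    structure(list(kind = kind, records = recs, labels = labels,
                   meta = list()), class = "task_fixture")
  } else if (kind == "torsion_angles") {
    recs <- read_fasta(file.path(dir, "sequences.fasta"))
    labels <- lapply(names(recs), function(id)
      as.matrix(read.table(file.path(dir, paste0(id, ".tsv")), header = TRUE,
                           sep = "\t")))
    labels <- lapply(labels, function(M) { dimnames(M) <- NULL; M })
    structure(list(kind = kind, records = recs, labels = labels,
                   meta = list()), class = "task_fixture")
  } else stop_usage("unsupported fixture kind: ", kind)
}
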