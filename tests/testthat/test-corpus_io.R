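test_that("FASTA round trip is the identity and wrapping is respected", {
  recs <- c(seq_a = paste(rep("ACGU", 40), collapse = ""),
            seq_b = "AUGCUUAGGCA")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, wrap = 60)
  back <- read_fasta(f)
  expect_identical(back, recs)

  # wrapped lines: 160-nt record at wrap 60 -> ceiling(160/60) = 3 lines
  lines <- readLines(f)
  expect_equal(sum(grepl("^[ACGU]+$", lines[2:4])), 3)

  # character-count oracle over the raw file
  seq_lines <- lines[!startsWith(lines, ">")]
  expect_equal(sum(nchar(seq_lines)), sum(nchar(recs)))

  # wrap 10, length 25 -> 3 sequence lines
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(x = random_seq(25)), f2, wrap = 10)
  expect_equal(sum(!startsWith(readLines(f2), ">")), 3)

  # empty corpus -> empty file -> empty corpus
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(setNames(character(0), character(0)), f3)
  expect_length(read_fasta(f3), 0)

  expect_error(read_fasta(file.path(tempdir(), "no_such.fasta")), "no such file")
})

test_that("normalization uppercases, maps T to U, and applies the ambiguity policy", {
  expect_equal(normalize_sequence("acgt"), "ACGU")
  expect_equal(as.character(normalize_sequence("ACGN", "replace")), "ACGN")
  expect_equal(attr(normalize_sequence("ACGN", "replace"), "n_ambiguous"), 1)
  expect_equal(normalize_sequence("AC-G", "drop"), "ACG")
  expect_error(normalize_sequence("ACXG", "reject"), "position 3")
  # idempotence
  x <- normalize_sequence(c("acgtn-", "TTTT"), "replace")
  expect_equal(as.character(normalize_sequence(as.character(x), "replace")),
               as.character(x))
})

test_that("corpus generation is deterministic and matches spec frequencies", {
  spec <- corpus_spec(50, length_model = length_uniform(40, 120), seed = 5)
  expect_identical(generate_corpus(spec), generate_corpus(spec))

  # empirical base frequencies within 3 binomial standard errors at ~1e6 nt
  p <- rna_base_frequencies()
  spec2 <- corpus_spec(2000, base_frequencies = p,
                       length_model = length_fixed(500), seed = 17)
  corpus <- generate_corpus(spec2)
  n_total <- sum(nchar(corpus))
  chars <- strsplit(paste(corpus, collapse = ""), "")[[1]]
  obs <- table(factor(chars, levels = c("A", "C", "G", "U"))) / n_total
  se <- sqrt(p * (1 - p) / n_total)
  expect_true(all(abs(as.numeric(obs) - p) < 3 * se))

  expect_length(generate_corpus(corpus_spec(0, seed = 1)), 0)
  expect_error(corpus_spec(5, length_model = length_fixed(4),
                           motif_set = list(list(motif = "ACGUACGU", prob = 1))),
               "degenerate")
  expect_error(corpus_spec(5, base_frequencies = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
})

test_that("motifs are planted at the stated probability", {
  m <- "GGACUAGCGGAU"
  spec <- corpus_spec(400, length_model = length_fixed(60),
                      motif_set = list(list(motif = m, prob = 0.5)), seed = 3)
  corpus <- generate_corpus(spec)
  hit <- mean(grepl(m, corpus, fixed = TRUE))
  expect_gt(hit, 0.40)
  expect_lt(hit, 0.60)
})

test_that("pair-interaction fixtures are balanced and Bayes-learnable", {
  fx <- generate_task_fixture("pair_interaction", n = 200, seed = 42)
  balance <- mean(fx$labels)
  expect_gte(balance, 0.4)
  expect_lte(balance, 0.6)
  # Bayes-optimal rule on the planted signal: motif in first AND its reverse
  # complement in second
  m <- fx$meta$motif
  pred <- as.integer(grepl(m, fx$records$first, fixed = TRUE) &
                       grepl(revcomp_rna(m), fx$records$second, fixed = TRUE))
  expect_gt(mean(pred == fx$labels), 0.9)
})

test_that("pairing maps are symmetric with zero diagonal and single partners", {
  fx <- generate_task_fixture("pairing_map", n = 20, seed = 7)
  for (M in fx$labels) {
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
    expect_true(all(rowSums(M) <= 1))
    expect_gt(sum(M), 0)
  }
  # paired positions carry complementary bases
  s <- strsplit(fx$records[[1]], "")[[1]]
  M <- fx$labels[[1]]
  idx <- which(M == 1, arr.ind = TRUE)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  expect_true(all(s[idx[, 1]] == comp[s[idx[, 2]]]))
})

test_that("distance maps are symmetric nonnegative; torsion fixtures behave", {
  fx <- generate_task_fixture("distance_map", n = 5, seed = 8)
  for (M in fx$labels) {
    expect_identical(M, t(M))
    expect_true(all(M >= 0))
    expect_true(all(diag(M) == 0))
  }
  # zero-noise torsion: angles are an exact function of the sequence
  f1 <- generate_task_fixture("torsion_angles", n = 4, seed = 1, noise_sd = 0)
  for (a in f1$labels) {
    expect_true(all(a > -180 & a <= 180))
  }
  f3 <- generate_task_fixture("torsion_angles", n = 4, seed = 1, noise_sd = 0)
  expect_identical(f1$labels, f3$labels)
})

test_that("fixtures serialize to text and back", {
  d1 <- withr::local_tempdir()
  fx <- generate_task_fixture("pair_interaction", n = 12, seed = 2)
  write_fixture(fx, d1)
  back <- read_fixture(d1)
  expect_equal(back$labels, fx$labels)
  expect_equal(unname(back$records$first), unname(fx$records$first))

  d2 <- withr::local_tempdir()
  fx2 <- generate_task_fixture("pairing_map", n = 3, seed = 2)
  write_fixture(fx2, d2)
  back2 <- read_fixture(d2)
  expect_equal(back2$labels, fx2$labels)

  d3 <- withr::local_tempdir()
  fx3 <- generate_task_fixture("torsion_angles", n = 2, seed = 2)
  write_fixture(fx3, d3)
  back3 <- read_fixture(d3)
  expect_equal(back3$labels, fx3$labels, tolerance = 1e-6)
})
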