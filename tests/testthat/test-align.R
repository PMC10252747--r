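test_that("single-residue alignment returns the matrix entry", {
  aln <- needleman_wunsch("A", "A")
  expect_equal(aln$aligned_a, "A")
  expect_equal(aln$aligned_b, "A")
  expect_equal(aln$score, blosum62["A", "A"], ignore_attr = TRUE)
})

test_that("empty sequences and unknown residues are rejected", {
  expect_error(needleman_wunsch("A", ""), "non-empty")
  expect_error(needleman_wunsch("", "A"), "non-empty")
  expect_error(needleman_wunsch("AO", "A"), "O")
})

test_that("DP score equals exhaustive enumeration over all global alignments", {
  set.seed(501)
  for (k in 1:60) {
    a <- random_protein(sample(1:6, 1))
    b <- random_protein(sample(1:6, 1))
    aln <- needleman_wunsch(a, b)
    expect_equal(aln$score, enumerate_nw_score(a, b, blosum62))
    # reported alignment recovers the inputs and scores to its own score
    expect_equal(gsub("-", "", aln$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", aln$aligned_b, fixed = TRUE), b)
    expect_equal(score_alignment(aln$aligned_a, aln$aligned_b,
                                 blosum62, 10, 1), aln$score)
    expect_false(any(substring(aln$aligned_a,
                               seq_len(nchar(aln$aligned_a)),
                               seq_len(nchar(aln$aligned_a))) == "-" &
                     substring(aln$aligned_b,
                               seq_len(nchar(aln$aligned_b)),
                               seq_len(nchar(aln$aligned_b))) == "-"))
  }
})

test_that("DP score matches Biostrings pairwiseAlignment on random pairs", {
  set.seed(502)
  for (k in 1:25) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    bs <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = blosum62, gapOpening = 10, gapExtension = 1,
      type = "global"))
    expect_equal(needleman_wunsch(a, b)$score, bs)
  }
})

test_that("alignment score is symmetric and beats hand-built alignments", {
  set.seed(503)
  for (k in 1:20) {
    a <- random_protein(sample(2:12, 1))
    b <- random_protein(sample(2:12, 1))
    expect_equal(needleman_wunsch(a, b)$score, needleman_wunsch(b, a)$score)
    # a trivial all-columns alignment padded with terminal gaps never wins
    pad_a <- paste0(a, strrep("-", nchar(b)))
    pad_b <- paste0(strrep("-", nchar(a)), b)
    expect_gte(needleman_wunsch(a, b)$score,
               score_alignment(pad_a, pad_b, blosum62, 10, 1))
  }
})

test_that("percent identity follows both denominator conventions", {
  ident <- needleman_wunsch("PASTA", "PASTA")
  expect_equal(percent_identity(ident), 100)
  expect_equal(percent_identity(ident, "shorter_sequence"), 100)

  aln <- list(aligned_a = "AR-C", aligned_b = "ARDC")
  expect_equal(percent_identity(aln), 100)  # gap column excluded
  expect_equal(percent_identity(aln, "shorter_sequence"), 100)

  aln2 <- list(aligned_a = "ARNC", aligned_b = "ARDC")
  expect_equal(percent_identity(aln2), 75)

  # identity of a fixed alignment does not depend on row order
  set.seed(504)
  for (k in 1:20) {
    aln <- needleman_wunsch(random_protein(sample(3:15, 1)),
                            random_protein(sample(3:15, 1)))
    swapped <- list(aligned_a = aln$aligned_b, aligned_b = aln$aligned_a)
    expect_equal(percent_identity(aln), percent_identity(swapped))
  }

  expect_error(
    percent_identity(list(aligned_a = "-A", aligned_b = "A-")),
    "no gap-free columns"
  )
})

test_that("gap-column trimming removes exactly the at-threshold columns", {
  # 5 rows; column 2 has exactly one gap (20%): removed at the default
  msa <- c(r1 = "AC-A", r2 = "ACCA", r3 = "ACCA", r4 = "ACCA", r5 = "ACCA")
  msa[1] <- "A-CA"
  trimmed <- trim_gappy_columns(msa)
  expect_equal(unname(trimmed), c("ACA", "ACA", "ACA", "ACA", "ACA"))
  expect_equal(names(trimmed), names(msa))

  gapless <- c(a = "PAST", b = "PAST")
  expect_equal(trim_gappy_columns(gapless), gapless)
  expect_error(trim_gappy_columns(character(0)), "empty alignment")
})

test_that("trimming is idempotent and every retained column re-verifies", {
  set.seed(505)
  for (k in 1:25) {
    msa <- random_msa(sample(3:12, 1), sample(10:60, 1))
    trimmed <- trim_gappy_columns(msa)
    expect_identical(trim_gappy_columns(trimmed), trimmed)
    if (nchar(trimmed[[1]]) > 0) {
      expect_true(all(gap_fractions(trimmed) < 0.20))
    }
    # and every removed column was at or above threshold
    removed <- sum(gap_fractions(msa) >= 0.20)
    expect_equal(nchar(msa[[1]]) - nchar(trimmed[[1]]), removed)
  }
})

test_that("aligned FASTA I/O validates shape and gap dialect", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "PA-T", ">b", "PAST"), path)
  msa <- read_alignment(path)
  expect_equal(unname(msa), c("PA-T", "PAST"))
  write_alignment(msa, path)
  expect_identical(read_alignment(path), msa)

  writeLines(c(">a", "PA.T", ">b", "PAST"), path)
  expect_error(read_alignment(path), "'\\.' gap symbol")
  writeLines(c(">a", "PAT", ">b", "PAST"), path)
  expect_error(read_alignment(path), "ragged.*record b")
})

test_that("queries go to the reference of maximal identity, ties by order", {
  refs <- protein_records(c("R1", "R2"),
                          c("PASTPASTPAST", "GWGWGWGWGWGW"))
  q <- protein_records("q", "PASTPASTPAST")
  g <- nearest_reference_grouping(q, refs)
  expect_equal(g$reference, "R1")
  expect_equal(g$identity, 100)

  # equidistant: two identical references, first listed wins
  refs2 <- protein_records(c("first", "second"),
                           c("PASTPAST", "PASTPAST"))
  g2 <- nearest_reference_grouping(q, refs2)
  expect_equal(g2$reference, "first")

  expect_error(
    nearest_reference_grouping(q, protein_records(character(0), character(0))),
    "at least one reference"
  )
})

test_that("grouping agrees with the all-pairs brute force and ignores query order", {
  set.seed(506)
  for (k in 1:5) {
    queries <- protein_records(sprintf("q%d", 1:4),
                               replicate(4, random_protein(sample(8:20, 1))))
    refs <- protein_records(sprintf("r%d", 1:3),
                            replicate(3, random_protein(sample(8:20, 1))))
    g <- nearest_reference_grouping(queries, refs)
    expect_equal(g, brute_group(queries, refs))
    perm <- sample(4)
    gp <- nearest_reference_grouping(queries[perm, ], refs)
    expect_equal(gp[order(gp$query), ], g[order(g$query), ],
                 ignore_attr = TRUE)
  }
})
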