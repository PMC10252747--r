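test_that("the textbook template sequence is called with its hand-derived cleavage", {
  # M + basic KK + ten-L h-region + A G A c-region, then mature residues:
  # rules (a)-(d) hold and the leftmost von Heijne site is position 16.
  call <- predict_signal_peptide(paste0("MKKLLLLLLLLLLAGA", "SESESESE"))
  expect_true(call$present)
  expect_equal(call$cleavage_pos, 16L)
  expect_equal(call$source, "builtin")
})

test_that("sequences failing individual rules are called absent", {
  # no basic residue, no hydrophobic core
  expect_false(predict_signal_peptide(
    paste0("M", strrep("E", 30)))$present)
  # below the minimum length: absent, not an error
  expect_false(predict_signal_peptide("MKPAST")$present)
  # first residue not M
  expect_false(predict_signal_peptide(
    paste0("KKKLLLLLLLLLLAGA", "SESESESE"))$present)
  # hydrophobic core present but no small -3/-1 site in range
  expect_false(predict_signal_peptide(
    paste0("MKKLLLLLLLLLLEEE", "EEEEEEEEEEEEEEEEEEEEEE"))$present)
})

test_that("calls are deterministic and never present without an initiator M", {
  set.seed(301)
  for (k in 1:100) {
    s <- random_protein(sample(10:80, 1))
    c1 <- predict_signal_peptide(s)
    expect_identical(c1, predict_signal_peptide(s))
    if (substr(s, 1, 1) != "M") expect_false(c1$present)
  }
})

test_that("reported cleavage sites always satisfy the (-3,-1) small-residue rule", {
  small <- c("A", "G", "S", "C", "T", "V")
  set.seed(302)
  n_present <- 0
  for (k in 1:400) {
    # bias draws toward the SP template so a usable fraction is present
    s <- paste0("M", random_protein(1), paste(sample(c("L", "I", "V", "A", "K", "R", "G", "S"),
                                                     sample(14:30, 1), replace = TRUE), collapse = ""))
    call <- predict_signal_peptide(s)
    if (call$present) {
      n_present <- n_present + 1
      p <- call$cleavage_pos
      expect_gte(p, 15L)
      expect_lte(p, 34L)
      expect_lt(p, nchar(s))
      expect_true(substr(s, p - 2, p - 2) %in% small)
      expect_true(substr(s, p, p) %in% small)
    }
  }
  expect_gt(n_present, 10)  # the property was actually exercised
})

test_that("external prediction tables are parsed, with and without header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsp_present\tcleavage_pos",
               "q1\t1\t22", "q2\t0\t", "q3\ttrue\t18"), path)
  calls <- load_external_calls(path)
  expect_named(calls, c("q1", "q2", "q3"))
  expect_true(calls$q1$present)
  expect_equal(calls$q1$cleavage_pos, 22L)
  expect_equal(calls$q1$source, "external")
  expect_false(calls$q2$present)
  expect_true(is.na(calls$q2$cleavage_pos))

  writeLines(c("q9\t1\t20"), path)  # headerless
  expect_true(load_external_calls(path)$q9$present)
})

test_that("malformed external rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsp_present\tcleavage_pos", "q1\tmaybe\t10"), path)
  expect_error(load_external_calls(path), "line 2")
  writeLines(c("q1\t0\t12"), path)
  expect_error(load_external_calls(path), "sp_present is false at line 1")
  writeLines(c("q1"), path)
  expect_error(load_external_calls(path), "malformed.*line 1")
})

test_that("external calls override the builtin heuristic during a scan", {
  rec <- protein_records(
    c("withsp", "plain"),
    c(paste0("MKKLLLLLLLLLLAGA", strrep("PA", 30)), strrep("PA", 30))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsp_present\tcleavage_pos",
               "withsp\t0\t", "plain\t1\t16", "ghost\t1\t20"), path)
  calls <- load_external_calls(path)
  expect_warning(res <- scan_proteome(rec, external_calls = calls),
                 "ghost")
  expect_false(res$results$sp_present[res$results$id == "withsp"])
  expect_true(res$results$sp_present[res$results$id == "plain"])
})
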