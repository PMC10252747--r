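# Independent oracles and fixture builders used across the suite.

random_protein <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Brute-force dipeptide scan: check every position against every motif.
naive_scan <- function(residues, motifs = AGP_MOTIFS) {
  starts <- integer(0)
  found <- character(0)
  n <- nchar(residues)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      di <- substr(residues, i, i + 1L)
      for (m in motifs) {
        if (di == m) {
          starts <- c(starts, i)
          found <- c(found, m)
        }
      }
    }
  }
  data.frame(motif = found, start = starts, stringsAsFactors = FALSE)
}

# Score one explicit global alignment under affine penalties: each
# maximal gap run of length L costs open + L * ext.
score_alignment <- function(aa, bb, sub, open, ext) {
  ca <- strsplit(aa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(bb, "", fixed = TRUE)[[1L]]
  score <- 0
  run <- ""  # current gap-run orientation: "", "a", or "b"
  for (k in seq_along(ca)) {
    if (ca[[k]] == "-") {
      score <- score - ext - if (run == "a") 0 else open
      run <- "a"
    } else if (cb[[k]] == "-") {
      score <- score - ext - if (run == "b") 0 else open
      run <- "b"
    } else {
      score <- score + sub[ca[[k]], cb[[k]]]
      run <- ""
    }
  }
  score
}

# Exhaustively enumerate every global alignment of a and b (no gap-gap
# columns) and return the maximum affine score.  Tractable for length <= 6.
enumerate_nw_score <- function(a, b, sub, open = 10, ext = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- -Inf
  rec <- function(i, j, aa, bb) {
    if (i > length(ca) && j > length(cb)) {
      s <- score_alignment(paste(aa, collapse = ""),
                           paste(bb, collapse = ""), sub, open, ext)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1L, j + 1L, c(aa, ca[[i]]), c(bb, cb[[j]]))
    }
    if (i <= length(ca)) rec(i + 1L, j, c(aa, ca[[i]]), c(bb, "-"))
    if (j <= length(cb)) rec(i, j + 1L, c(aa, "-"), c(bb, cb[[j]]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  get("BLOSUM62", envir = env)
})

# All-pairs identity table maximisation: the grouping oracle.
brute_group <- function(queries, references, mode = "aligned_columns") {
  out <- data.frame(query = character(0), reference = character(0),
                    identity = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(queries))) {
    tab <- numeric(0)
    for (j in seq_len(nrow(references))) {
      aln <- needleman_wunsch(queries$residues[[i]],
                              references$residues[[j]])
      tab <- c(tab, percent_identity(aln, mode))
    }
    best <- which(tab == max(tab))[[1L]]
    out <- rbind(out, data.frame(
      query = queries$id[[i]], reference = references$id[[best]],
      identity = tab[[best]], stringsAsFactors = FALSE
    ))
  }
  out
}

# Random toy alignment: n_rows x n_cols with i.i.d. per-cell gap
# probability; no all-gap rows enforced (rare and harmless).
random_msa <- function(n_rows, n_cols, gap_prob = 0.15) {
  rows <- vapply(seq_len(n_rows), function(r) {
    chars <- sample(AA_STANDARD, n_cols, replace = TRUE)
    gaps <- stats::runif(n_cols) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  stats::setNames(rows, sprintf("row%02d", seq_len(n_rows)))
}

# Per-column gap-fraction recount straight off the character matrix.
gap_fractions <- function(msa) {
  chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  colMeans(chars == "-")
}
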