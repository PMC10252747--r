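#' Background amino-acid frequencies
#'
#' Average composition of a well-annotated protein database (Swiss-Prot
#' release statistics, rounded), embedded as a constant so that fixture
#' generation needs no downloads.  The P+A+S+T mass is about 25%, far
#' below the 50% classical-AGP threshold.
#'
#' @format Named numeric vector over the 20 standard residues; sums to 1.
#' @export
BACKGROUND_FREQS <- local({
  f <- c(
    A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38,
    Q = 3.93, E = 6.72, G = 7.07, H = 2.27, I = 5.91,
    L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
    S = 6.64, T = 5.36, W = 1.10, Y = 2.92, V = 6.86
  )
  f / sum(f)
})

#' Parameters of the synthetic-proteome generator
#'
#' Defaults define the benchmark conditions used throughout the test
#' suite: mature regions of 120 residues with PAST fraction drawn
#' uniformly in \[0.6, 0.85\] and 6 planted motifs (two more than the
#' classifier's default `min_repeats`), against background proteins of
#' 100-400 residues at average composition.
#'
#' @param mature_length Length of generated mature regions (default 120).
#' @param past_range `c(min, max)` for the PAST fraction of planted AGP
#'   mature regions (default `c(0.6, 0.85)`).
#' @param decoy_past Low PAST fraction used by the `decoy_low_past` class
#'   (default 0.25, the background level).
#' @param n_motifs Number of planted dipeptide motifs (default 6).
#' @param background_length `c(min, max)` uniform range for background
#'   protein lengths (default `c(100, 400)`).
#' @return List of class `synth_params`.
#' @export
synth_params <- function(mature_length = 120L,
                         past_range = c(0.6, 0.85),
                         decoy_past = 0.25,
                         n_motifs = 6L,
                         background_length = c(100L, 400L)) {
  p <- structure(list(
    mature_length = as.integer(mature_length),
    past_range = past_range,
    decoy_past = decoy_past,
    n_motifs = as.integer(n_motifs),
    background_length = as.integer(background_length)
  ), class = "synth_params")
  if (p$mature_length < 2L * p$n_motifs) {
    stop_config("mature_length ", p$mature_length,
                " too short to host ", p$n_motifs, " planted motifs")
  }
  p
}

#' Draw a background protein sequence
#'
#' Residues are drawn i.i.d. from [BACKGROUND_FREQS]; the expected PAST
#' percentage is about 25.  Uses the current RNG state (seed upstream).
#'
#' @param length Sequence length (>= 1).
#' @return A sequence string.
#' @export
generate_background <- function(length) {
  if (length < 1L) stop_config("length must be >= 1, got ", length)
  paste(sample(names(BACKGROUND_FREQS), length, replace = TRUE,
               prob = BACKGROUND_FREQS), collapse = "")
}

# A signal peptide built to satisfy the built-in heuristic exactly:
# M + two basic residues + hydrophobic run (L/I/F, so no residue of the
# run can masquerade as a -3/-1 small residue) + a 4-residue c-region
# x A y A with x, y polar.  The heuristic then cleaves exactly at the
# final A, so the mature region is exactly what the caller appends.
generate_signal_peptide <- function() {
  run_len <- sample(8:12, 1L)
  paste0(
    "M",
    paste(sample(c("K", "R"), 2L, replace = TRUE), collapse = ""),
    paste(sample(c("L", "I", "F"), run_len, replace = TRUE), collapse = ""),
    sample(c("Q", "E", "N"), 1L), "A",
    sample(c("Q", "E", "N"), 1L), "A"
  )
}

# Filler with an exact PAST residue count: round(past_frac * n) residues
# drawn from {P,A,S,T}, the rest from the background non-PAST residues,
# positions shuffled.  Exact counts (not Bernoulli draws) make the
# composition criterion deterministic for planted classes.
generate_filler <- function(n, past_frac) {
  if (n == 0L) return("")
  n_past <- round(past_frac * n)
  non_past <- BACKGROUND_FREQS[setdiff(names(BACKGROUND_FREQS),
                                       c("P", "A", "S", "T"))]
  chars <- c(
    sample(c("P", "A", "S", "T"), n_past, replace = TRUE),
    sample(names(non_past), n - n_past, replace = TRUE,
           prob = non_past)
  )
  paste(sample(chars), collapse = "")
}

# Mature region with n_motifs planted dipeptides interleaved into exact-
# composition filler at seeded random cut points.
generate_mature_body <- function(params, past_frac) {
  n_motifs <- params$n_motifs
  filler_len <- params$mature_length - 2L * n_motifs
  motifs <- sample(AGP_MOTIFS, n_motifs, replace = TRUE)
  cuts <- sort(sample(0:filler_len, n_motifs, replace = TRUE))
  chunk_len <- diff(c(0L, cuts, filler_len))
  filler <- strsplit(generate_filler(filler_len, past_frac),
                     "", fixed = TRUE)[[1L]]
  parts <- character(0)
  at <- 0L
  for (k in seq_len(n_motifs)) {
    parts <- c(parts,
               paste(filler[seq_len(chunk_len[[k]]) + at], collapse = ""),
               motifs[[k]])
    at <- at + chunk_len[[k]]
  }
  paste0(paste(parts, collapse = ""),
         paste(filler[seq_len(chunk_len[[n_motifs + 1L]]) + at],
               collapse = ""))
}

#' Generate one classical-AGP sequence
#'
#' Concatenates a signal peptide built to the heuristic's template with a
#' PAST-rich mature region carrying planted AP/PA/SP/TP motifs.  By
#' construction the result satisfies all three classifier criteria at
#' default parameters.
#'
#' @param params A [synth_params()] list.
#' @return A sequence string.
#' @export
generate_classical_agp <- function(params = synth_params()) {
  past_frac <- stats::runif(1L, params$past_range[[1L]],
                            params$past_range[[2L]])
  paste0(generate_signal_peptide(), generate_mature_body(params, past_frac))
}

#' Generate a single-criterion decoy sequence
#'
#' Each decoy violates exactly one classifier criterion and satisfies the
#' other two: `decoy_no_sp` is a PAST-rich repeat-rich body with no
#' signal peptide (first residue forced non-M); `decoy_low_past` has a
#' signal peptide and planted repeats but background-level PAST;
#' `decoy_no_repeats` has a signal peptide and a pure-PAST mature region
#' built from homopolymer runs of P, S, T and A whose junctions (PS, ST,
#' TA) form none of the four motifs.
#'
#' @param kind One of `"decoy_no_sp"`, `"decoy_low_past"`,
#'   `"decoy_no_repeats"`.
#' @param params A [synth_params()] list.
#' @return A sequence string.
#' @export
generate_decoy <- function(kind, params = synth_params()) {
  switch(kind,
    decoy_no_sp = {
      past_frac <- stats::runif(1L, params$past_range[[1L]],
                                params$past_range[[2L]])
      body <- generate_mature_body(params, past_frac)
      if (substr(body, 1L, 1L) == "M") substr(body, 1L, 1L) <- "P"
      body
    },
    decoy_low_past = {
      paste0(generate_signal_peptide(),
             generate_mature_body(params, params$decoy_past))
    },
    decoy_no_repeats = {
      n <- params$mature_length
      lens <- c(rep(n %/% 4L, 3L), n - 3L * (n %/% 4L))
      paste0(generate_signal_peptide(),
             paste(strrep(c("P", "S", "T", "A"), lens), collapse = ""))
    },
    stop_config("unknown decoy kind: ", kind)
  )
}

#' Generate a seeded synthetic proteome with ground truth
#'
#' Produces a shuffled mixture of background proteins, planted classical
#' AGPs and single-criterion decoys, with exact truth labels.  The same
#' seed and parameters reproduce the same records byte-for-byte.
#'
#' @param n_background,n_agp,n_per_decoy_kind Class sizes (decoys are per
#'   kind: three kinds).  All zero is an error.
#' @param seed Integer seed driving all randomness.
#' @param params A [synth_params()] list.
#' @return List of class `synthetic_truth_set`: `records` (protein-record
#'   `data.frame`, shuffled order, ids `syn0001`...), `labels`
#'   (`data.frame` id/label), `seed`, `params`.
#' @examples
#' ts <- generate_proteome(10, 2, 1, seed = 1)
#' table(ts$labels$label)
#' @export
generate_proteome <- function(n_background, n_agp, n_per_decoy_kind,
                              seed, params = synth_params()) {
  if (n_background < 0L || n_agp < 0L || n_per_decoy_kind < 0L) {
    stop_config("counts must be >= 0")
  }
  total <- n_background + n_agp + 3L * n_per_decoy_kind
  if (total == 0L) stop_config("empty proteome: all counts are 0")
  with_seed(seed, {
    kinds <- c("decoy_no_sp", "decoy_low_past", "decoy_no_repeats")
    seqs <- c(
      vapply(seq_len(n_background), function(i) {
        generate_background(sample(params$background_length[[1L]]:
                                     params$background_length[[2L]], 1L))
      }, character(1)),
      vapply(seq_len(n_agp), function(i) generate_classical_agp(params),
             character(1)),
      unlist(lapply(kinds, function(k) {
        vapply(seq_len(n_per_decoy_kind), function(i) {
          generate_decoy(k, params)
        }, character(1))
      }))
    )
    labels <- c(
      rep("background", n_background),
      rep("agp", n_agp),
      rep(kinds, each = n_per_decoy_kind)
    )
    ord <- sample(total)
    seqs <- seqs[ord]
    labels <- labels[ord]
    ids <- sprintf("syn%04d", seq_len(total))
    structure(list(
      records = protein_records(ids, seqs),
      labels = data.frame(id = ids, label = labels,
                          stringsAsFactors = FALSE),
      seed = seed,
      params = params
    ), class = "synthetic_truth_set")
  })
}
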