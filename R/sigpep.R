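#' Parameters of the built-in signal-peptide heuristic
#'
#' The heuristic encodes the textbook tripartite architecture of
#' secretory signal peptides: a short positively charged n-region, a
#' hydrophobic h-region core, and a c-region ending at a cleavage site
#' that obeys the von Heijne (-3, -1) small-residue rule.  It is a
#' deterministic, self-contained stand-in for neural-network predictors;
#' for real analyses, external predictor output can be imported with
#' [load_external_calls()] and takes precedence.
#'
#' @param min_length Sequences shorter than this are called absent
#'   (default 15).
#' @param n_region_end Last position searched for a basic residue
#'   (default 6; the search covers positions 2..`n_region_end`).
#' @param basic_residues Residues accepted as basic (default K, R).
#' @param h_window Window width for the hydrophobic core (default 8).
#' @param h_span Positions `c(from, to)` the h-window must lie within
#'   (default 4..26).
#' @param h_threshold Minimum mean Kyte-Doolittle hydropathy over the
#'   window (default 1.6).
#' @param cleavage_range Allowed `c(min, max)` for the cleavage position,
#'   i.e. the last signal-peptide residue (default 15..34).
#' @param small_residues Residues allowed at the -3 and -1 positions of
#'   the cleavage site (default A, G, S, C, T, V).
#' @param hydropathy Named hydropathy scale (default [KYTE_DOOLITTLE]).
#' @return A list of class `sigpep_params`.
#' @export
sigpep_params <- function(min_length = 15L,
                          n_region_end = 6L,
                          basic_residues = c("K", "R"),
                          h_window = 8L,
                          h_span = c(4L, 26L),
                          h_threshold = 1.6,
                          cleavage_range = c(15L, 34L),
                          small_residues = c("A", "G", "S", "C", "T", "V"),
                          hydropathy = KYTE_DOOLITTLE) {
  structure(list(
    min_length = as.integer(min_length),
    n_region_end = as.integer(n_region_end),
    basic_residues = basic_residues,
    h_window = as.integer(h_window),
    h_span = as.integer(h_span),
    h_threshold = h_threshold,
    cleavage_range = as.integer(cleavage_range),
    small_residues = small_residues,
    hydropathy = hydropathy
  ), class = "sigpep_params")
}

sp_call <- function(present, cleavage_pos = NA_integer_, source = "builtin") {
  list(present = present, cleavage_pos = as.integer(cleavage_pos),
       source = source)
}

#' Predict signal-peptide presence and cleavage position
#'
#' A signal peptide is called present iff all four rules hold:
#' (a) the first residue is M (the initiator methionine);
#' (b) at least one basic residue (K/R) occurs at positions 2..6
#'     (n-region charge);
#' (c) some window of 8 consecutive residues lying entirely within
#'     positions 4..26 has mean Kyte-Doolittle hydropathy >= 1.6
#'     (h-region core);
#' (d) a cleavage position p exists with 15 <= p <= 34,
#'     p >= (end of the leftmost qualifying h-window) + 2 and
#'     p < sequence length, such that the residues at the -3 and -1
#'     positions of the cleavage site (sequence positions p-2 and p)
#'     are both small (A, G, S, C, T, V).  The smallest such p is the
#'     cleavage position: the last residue of the signal peptide.
#'
#' Sequences shorter than `min_length` are called absent, not an error.
#'
#' @param residues A single sequence string.
#' @param params A [sigpep_params()] list.
#' @return List with `present` (logical), `cleavage_pos` (integer, `NA`
#'   when absent) and `source = "builtin"`.
#' @examples
#' predict_signal_peptide(paste0("MKKLLLLLLLLLLAGA", "SESESESE"))
#' @export
predict_signal_peptide <- function(residues, params = sigpep_params()) {
  stopifnot(is.character(residues), length(residues) == 1L)
  p <- params
  n <- nchar(residues)
  if (n < p$min_length) return(sp_call(FALSE))
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  # (a) initiator methionine
  if (chars[[1L]] != "M") return(sp_call(FALSE))
  # (b) basic residue in the n-region
  n_reg <- chars[2L:min(p$n_region_end, n)]
  if (!any(n_reg %in% p$basic_residues)) return(sp_call(FALSE))
  # (c) hydrophobic h-region window
  kd <- unname(p$hydropathy[chars])
  span_to <- min(p$h_span[2L], n)
  last_start <- span_to - p$h_window + 1L
  if (last_start < p$h_span[1L]) return(sp_call(FALSE))
  h_end <- NA_integer_
  for (s in p$h_span[1L]:last_start) {
    if (mean(kd[s:(s + p$h_window - 1L)]) >= p$h_threshold) {
      h_end <- s + p$h_window - 1L
      break
    }
  }
  if (is.na(h_end)) return(sp_call(FALSE))
  # (d) von Heijne (-3, -1) rule; leftmost qualifying position wins
  lo <- max(p$cleavage_range[1L], h_end + 2L)
  hi <- min(p$cleavage_range[2L], n - 1L)
  if (lo > hi) return(sp_call(FALSE))
  for (pos in lo:hi) {
    if (chars[[pos - 2L]] %in% p$small_residues &&
        chars[[pos]] %in% p$small_residues) {
      return(sp_call(TRUE, pos))
    }
  }
  sp_call(FALSE)
}

#' Import external signal-peptide predictions
#'
#' Reads a tab-separated table of predictor output with columns
#' `id`, `sp_present` (0/1 or true/false) and `cleavage_pos` (integer,
#' empty when absent).  A header line is auto-detected.  When passed to
#' [scan_proteome()], external calls override the built-in heuristic for
#' matching ids.
#'
#' @param path Path to the TSV.
#' @return Named list mapping id to a call (`present`, `cleavage_pos`,
#'   `source = "external"`).
#' @export
load_external_calls <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  first <- tolower(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  offset <- 0L
  if (identical(first[1:2], c("id", "sp_present"))) {
    lines <- lines[-1L]
    offset <- 1L
  }
  calls <- list()
  for (i in seq_along(lines)) {
    lineno <- i + offset
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(f) < 2L || length(f) > 3L || !nzchar(f[[1L]])) {
      stop_data("malformed external-call row at line ", lineno)
    }
    pres <- switch(tolower(f[[2L]]),
                   "1" = TRUE, "true" = TRUE, "0" = FALSE, "false" = FALSE,
                   stop_data("malformed sp_present at line ", lineno,
                             ": '", f[[2L]], "'"))
    cleave <- if (length(f) == 3L && nzchar(f[[3L]])) {
      v <- suppressWarnings(as.integer(f[[3L]]))
      if (is.na(v)) stop_data("malformed cleavage_pos at line ", lineno)
      v
    } else NA_integer_
    if (!pres && !is.na(cleave)) {
      stop_data("cleavage_pos given while sp_present is false at line ",
                lineno)
    }
    if (f[[1L]] %in% names(calls)) {
      stop_data("duplicate id in external calls: ", f[[1L]])
    }
    calls[[f[[1L]]]] <- sp_call(pres, cleave, source = "external")
  }
  calls
}
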