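#' Parameters of the classical-AGP screen
#'
#' @param past_threshold Minimum PAST percentage (inclusive, default 50).
#' @param min_repeats Minimum number of dipeptide-motif hits in the
#'   mature region (inclusive, default 4).  The threshold itself is a
#'   package default: the classical criterion requires "presence and
#'   placement" of repeats without fixing a count.
#' @param motifs Dipeptide motif set (default [AGP_MOTIFS]).
#' @param biased_set Residues counted as biased (default P, A, S, T).
#' @param use_precursor If `TRUE`, the composition criterion is evaluated
#'   on the full precursor rather than the mature region, reproducing a
#'   strict two-stage reading in which the 50% screen precedes the
#'   signal-peptide check.  Default `FALSE`: a signal peptide is cleaved
#'   in vivo and its hydrophobic run would dilute the PAST percentage.
#' @param sigpep A [sigpep_params()] list for the built-in heuristic.
#' @return List of class `scan_params`.
#' @export
scan_params <- function(past_threshold = 50,
                        min_repeats = 4L,
                        motifs = AGP_MOTIFS,
                        biased_set = c("P", "A", "S", "T"),
                        use_precursor = FALSE,
                        sigpep = sigpep_params()) {
  if (is.na(past_threshold) || past_threshold < 0 || past_threshold > 100) {
    stop_config("past_threshold must be in [0, 100], got ", past_threshold)
  }
  if (is.na(min_repeats) || min_repeats < 0) {
    stop_config("min_repeats must be >= 0, got ", min_repeats)
  }
  structure(list(
    past_threshold = past_threshold,
    min_repeats = as.integer(min_repeats),
    motifs = motifs,
    biased_set = biased_set,
    use_precursor = isTRUE(use_precursor),
    sigpep = sigpep
  ), class = "scan_params")
}

#' Classify one protein as a classical-AGP candidate or not
#'
#' Applies the three classical criteria jointly: PAST composition at or
#' above the threshold, a signal-peptide call, and at least `min_repeats`
#' AP/PA/SP/TP motif hits starting within the mature region.  All three
#' are always evaluated, so `reasons` lists every violated criterion, not
#' just the first.
#'
#' When a signal peptide is called, the mature region is the sequence
#' after the cleavage position, and both composition (unless
#' `use_precursor`) and repeats are evaluated there; otherwise the full
#' sequence is used.
#'
#' @param id Record identifier (used in the result).
#' @param residues A single sequence string.
#' @param params A [scan_params()] list.
#' @param external_call Optional imported signal-peptide call for this
#'   protein; overrides the built-in heuristic.
#' @return List of class `agp_classification`: `id`, `length`,
#'   `sp_present`, `sp_cleavage`, `sp_source`, `past_percent_full`,
#'   `past_percent_mature`, `repeat_count`, `repeat_density`,
#'   `repeat_span`, `repeat_max_gap`, `verdict`
#'   (`"candidate"`/`"rejected"`) and `reasons` (character vector, empty
#'   iff candidate; codes `low_past`, `no_signal_peptide`,
#'   `insufficient_repeats`).
#' @export
classify_classical_agp <- function(id, residues, params = scan_params(),
                                   external_call = NULL) {
  n <- nchar(residues)
  call <- if (!is.null(external_call)) external_call
          else predict_signal_peptide(residues, params$sigpep)
  mature_start <- if (call$present && !is.na(call$cleavage_pos) &&
                      call$cleavage_pos < n) call$cleavage_pos + 1L else 1L
  mature <- c(mature_start, n)

  past_full <- past_percent(residues, NULL, params$biased_set)
  past_mature <- if (mature_start > 1L) {
    past_percent(residues, mature, params$biased_set)
  } else past_full

  hits <- scan_dipeptides(residues, mature, params$motifs)
  placement <- summarize_placement(hits, mature)

  past_for_verdict <- if (params$use_precursor) past_full else past_mature
  reasons <- character(0)
  if (past_for_verdict < params$past_threshold) reasons <- c(reasons, "low_past")
  if (!call$present) reasons <- c(reasons, "no_signal_peptide")
  if (placement$count < params$min_repeats) {
    reasons <- c(reasons, "insufficient_repeats")
  }

  structure(list(
    id = id,
    length = n,
    sp_present = call$present,
    sp_cleavage = if (call$present) call$cleavage_pos else NA_integer_,
    sp_source = call$source,
    past_percent_full = past_full,
    past_percent_mature = past_mature,
    repeat_count = placement$count,
    repeat_density = placement$density,
    repeat_span = placement$span_fraction,
    repeat_max_gap = placement$max_gap,
    verdict = if (length(reasons)) "rejected" else "candidate",
    reasons = reasons
  ), class = "agp_classification")
}

#' Screen a whole proteome for classical AGPs
#'
#' @param records Protein-record `data.frame` (see [read_fasta()]).  May
#'   have zero rows.
#' @param params A [scan_params()] list.
#' @param external_calls Optional named list from [load_external_calls()];
#'   ids absent from the proteome produce a warning, not an error.
#' @return List with `results` (one row per input protein, input order;
#'   columns as in the report TSV, `reasons` comma-joined) and `summary`
#'   (named counts: `n_total`, `n_candidate`, `n_rejected` and one count
#'   per failure reason).
#' @export
scan_proteome <- function(records, params = scan_params(),
                          external_calls = NULL) {
  if (!is.null(external_calls)) {
    orphan <- setdiff(names(external_calls), records$id)
    if (length(orphan)) {
      warning("external signal-peptide calls for unknown id(s): ",
              paste(orphan, collapse = ", "))
    }
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[[i]]
    cls <- classify_classical_agp(
      id, records$residues[[i]], params,
      external_call = external_calls[[id]]
    )
    data.frame(
      id = cls$id, length = cls$length,
      sp_present = cls$sp_present, sp_cleavage = cls$sp_cleavage,
      past_percent_full = cls$past_percent_full,
      past_percent_mature = cls$past_percent_mature,
      repeat_count = cls$repeat_count,
      repeat_density = cls$repeat_density,
      repeat_span = cls$repeat_span,
      verdict = cls$verdict,
      reasons = paste(cls$reasons, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  results <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      id = character(0), length = integer(0), sp_present = logical(0),
      sp_cleavage = integer(0), past_percent_full = numeric(0),
      past_percent_mature = numeric(0), repeat_count = integer(0),
      repeat_density = numeric(0), repeat_span = numeric(0),
      verdict = character(0), reasons = character(0),
      stringsAsFactors = FALSE
    )
  }
  reason_count <- function(code) sum(grepl(code, results$reasons, fixed = TRUE))
  summary <- list(
    n_total = nrow(results),
    n_candidate = sum(results$verdict == "candidate"),
    n_rejected = sum(results$verdict == "rejected"),
    low_past = reason_count("low_past"),
    no_signal_peptide = reason_count("no_signal_peptide"),
    insufficient_repeats = reason_count("insufficient_repeats")
  )
  list(results = results, summary = summary)
}
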