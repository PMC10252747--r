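#' PAST composition of a sequence region
#'
#' The classical-AGP composition criterion: the percentage of residues in
#' a region that are Pro, Ala, Ser or Thr.  `X` (unknown) residues count
#' in the denominator but never in the numerator, so uncertainty cannot
#' inflate a candidate's score.
#'
#' @param residues A single sequence string (uppercase residues).
#' @param region 1-based closed interval `c(start, end)`, or `NULL` for
#'   the full sequence.
#' @param biased_set Residues counted as biased; default `P, A, S, T`.
#' @return Percentage in `[0, 100]`, full floating precision.
#' @examples
#' past_percent("PASTGGGG")  # 50
#' past_percent("PX")        # 50: X dilutes, never counts
#' @export
past_percent <- function(residues, region = NULL,
                         biased_set = c("P", "A", "S", "T")) {
  stopifnot(is.character(residues), length(residues) == 1L)
  n <- nchar(residues)
  if (n == 0L) stop_config("empty sequence")
  reg <- check_region(region, n)
  chars <- strsplit(substr(residues, reg[1L], reg[2L]), "", fixed = TRUE)[[1L]]
  100 * sum(chars %in% biased_set) / length(chars)
}

#' Residue counts and PAST percentage for a region
#'
#' @inheritParams past_percent
#' @return List with `counts` (named integer vector over residues seen),
#'   `region_length`, and `past_percent`.
#' @export
composition_profile <- function(residues, region = NULL,
                                biased_set = c("P", "A", "S", "T")) {
  reg <- check_region(region, nchar(residues))
  chars <- strsplit(substr(residues, reg[1L], reg[2L]), "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = sort(unique(chars))))
  list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    region_length = length(chars),
    past_percent = 100 * sum(chars %in% biased_set) / length(chars)
  )
}
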