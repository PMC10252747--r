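#' Scan a region for AGP dipeptide motifs
#'
#' Reports every occurrence of the configured dipeptides, including
#' overlapping ones ("APA" contains both AP and PA): AGP repeat regions
#' are overlap-dense, and undercounting would bias against true AGPs.
#'
#' @param residues A single sequence string.
#' @param region 1-based closed interval `c(start, end)` or `NULL` for the
#'   full sequence.  A motif is reported when both its residues lie inside
#'   the region.
#' @param motifs Character vector of dipeptides; default [AGP_MOTIFS].
#' @return `data.frame` with columns `motif` and `start` (1-based index of
#'   the motif's first residue), sorted by `start`.
#' @examples
#' scan_dipeptides("APAP")  # AP at 1, PA at 2, AP at 3
#' @export
scan_dipeptides <- function(residues, region = NULL, motifs = AGP_MOTIFS) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (any(nchar(motifs) != 2L)) {
    stop_config("motifs must all have length 2: ",
                paste(motifs[nchar(motifs) != 2L], collapse = ", "))
  }
  reg <- check_region(region, nchar(residues))
  starts <- integer(0)
  found <- character(0)
  if (reg[2L] - reg[1L] + 1L >= 2L) {
    pos <- reg[1L]:(reg[2L] - 1L)
    di <- substring(residues, pos, pos + 1L)
    hit <- di %in% motifs
    starts <- pos[hit]
    found <- di[hit]
  }
  data.frame(motif = found, start = starts, stringsAsFactors = FALSE)
}

#' Summarise the placement of motif hits within a region
#'
#' Placement statistics quantify whether motifs are genuinely repeated
#' along the backbone: `count`, `density` (hits per 100 residues of the
#' region), `span_fraction` (distance between first and last hit start
#' over region length; 0 with fewer than 2 hits) and `max_gap` (largest
#' distance between consecutive hit starts; 0 with fewer than 2 hits).
#'
#' @param hits Hit `data.frame` from [scan_dipeptides()].
#' @param region 1-based closed interval `c(start, end)` the hits belong
#'   to.
#' @return List with `count`, `density`, `span_fraction`, `max_gap`.
#' @export
summarize_placement <- function(hits, region) {
  if (length(region) != 2L || region[1L] > region[2L]) {
    stop_config("region must be a non-empty c(start, end) interval")
  }
  region_len <- region[2L] - region[1L] + 1L
  starts <- sort(hits$start)
  if (length(starts) &&
      (starts[1L] < region[1L] || starts[length(starts)] + 1L > region[2L])) {
    stop_config("hit outside region [", region[1L], ", ", region[2L], "]")
  }
  n <- length(starts)
  list(
    count = n,
    density = 100 * n / region_len,
    span_fraction = if (n >= 2L) (starts[n] - starts[1L]) / region_len else 0,
    max_gap = if (n >= 2L) max(diff(starts)) else 0L
  )
}
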