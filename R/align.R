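#' Needleman-Wunsch global alignment with affine gap penalties
#'
#' Three-state Gotoh dynamic programming over a substitution matrix.  A
#' gap run of length L costs `gap_open + L * gap_extend`; runs of
#' opposite orientation that abut each other each pay the opening cost.
#' Traceback is deterministic: on score ties the diagonal (match) state
#' is preferred over a vertical gap (gap in `b`), which is preferred over
#' a horizontal gap (gap in `a`).
#'
#' @param a,b Non-empty sequence strings.
#' @param matrix A substitution matrix (residues x residues), or the name
#'   of one shipped with Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative gap penalties (defaults 10
#'   and 1).
#' @return List of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length strings over residues plus `-`; no column is gap-gap)
#'   and `score`.
#' @examples
#' needleman_wunsch("HEAGAWGHEE", "PAWHEAE")
#' @export
needleman_wunsch <- function(a, b, matrix = "BLOSUM62",
                             gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop_config("sequences must be non-empty")
  sub <- substitution_matrix(matrix)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(c(ca, cb), rownames(sub))
  if (length(unknown)) {
    stop_data("residue(s) absent from the substitution matrix: ",
              paste(unknown, collapse = ", "))
  }
  n <- length(ca)
  m <- length(cb)
  NEG <- -Inf
  # State 1 = M (diagonal), 2 = Ix (vertical: gap in b, consumes a),
  # 3 = Iy (horizontal: gap in a, consumes b).
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  pM <- matrix(0L, n + 1L, m + 1L)
  pIx <- matrix(0L, n + 1L, m + 1L)
  pIy <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n) {
    Ix[2L:(n + 1L), 1L] <- -(gap_open + gap_extend * seq_len(n))
    pIx[2L:(n + 1L), 1L] <- c(1L, rep(2L, n - 1L))
  }
  if (m) {
    Iy[1L, 2L:(m + 1L)] <- -(gap_open + gap_extend * seq_len(m))
    pIy[1L, 2L:(m + 1L)] <- c(1L, rep(3L, m - 1L))
  }
  for (i in seq_len(n)) {
    si <- sub[ca[[i]], cb]  # row of scores against all of b
    for (j in seq_len(m)) {
      prev <- c(M[i, j], Ix[i, j], Iy[i, j])
      k <- which.max(prev)  # first max: diagonal > vertical > horizontal
      M[i + 1L, j + 1L] <- prev[[k]] + si[[j]]
      pM[i + 1L, j + 1L] <- k
      up <- c(M[i, j + 1L] - gap_open, Ix[i, j + 1L],
              Iy[i, j + 1L] - gap_open) - gap_extend
      k <- which.max(up)
      Ix[i + 1L, j + 1L] <- up[[k]]
      pIx[i + 1L, j + 1L] <- k
      left <- c(M[i + 1L, j] - gap_open, Ix[i + 1L, j] - gap_open,
                Iy[i + 1L, j]) - gap_extend
      k <- which.max(left)
      Iy[i + 1L, j + 1L] <- left[[k]]
      pIy[i + 1L, j + 1L] <- k
    }
  }
  finals <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  state <- which.max(finals)
  score <- finals[[state]]
  # Traceback
  out_a <- character(0)
  out_b <- character(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      out_a <- c(ca[[i]], out_a)
      out_b <- c(cb[[j]], out_b)
      state <- pM[i + 1L, j + 1L]
      i <- i - 1L
      j <- j - 1L
    } else if (state == 2L) {
      out_a <- c(ca[[i]], out_a)
      out_b <- c("-", out_b)
      state <- pIx[i + 1L, j + 1L]
      i <- i - 1L
    } else {
      out_a <- c("-", out_a)
      out_b <- c(cb[[j]], out_b)
      state <- pIy[i + 1L, j + 1L]
      j <- j - 1L
    }
  }
  structure(list(
    aligned_a = paste(out_a, collapse = ""),
    aligned_b = paste(out_b, collapse = ""),
    score = score
  ), class = "pairwise_alignment")
}

# Resolve a substitution matrix given by name (from Biostrings) or as a
# numeric matrix.
substitution_matrix <- function(matrix) {
  if (is.character(matrix) && length(matrix) == 1L) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    get(matrix, envir = env)
  } else if (is.matrix(matrix) && is.numeric(matrix)) {
    matrix
  } else {
    stop_config("matrix must be a numeric matrix or a Biostrings matrix name")
  }
}

#' Percent identity of a pairwise alignment
#'
#' Two denominator conventions are exposed because reported family
#' identities rarely state one: `aligned_columns` divides identical
#' columns by the number of columns where neither row has a gap (the
#' default); `shorter_sequence` divides by the length of the shorter
#' ungapped sequence.
#'
#' @param alignment A `pairwise_alignment` (or any list with `aligned_a`
#'   and `aligned_b` of equal length).
#' @param mode `"aligned_columns"` or `"shorter_sequence"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(alignment,
                             mode = c("aligned_columns", "shorter_sequence")) {
  mode <- match.arg(mode)
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) {
    stop_data("aligned sequences differ in length")
  }
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop_data("alignment has no gap-free columns")
  ident <- sum(ca == cb & both)
  denom <- switch(mode,
    aligned_columns = sum(both),
    shorter_sequence = min(sum(ca != "-"), sum(cb != "-"))
  )
  100 * ident / denom
}

#' Read an aligned FASTA file as a multiple sequence alignment
#'
#' @param path Path to aligned FASTA.  All rows must have equal length;
#'   the only gap symbol accepted is `-` (a `.` gap is rejected with a
#'   message, as it is a different alignment dialect).
#' @return Named character vector of equal-length aligned sequences
#'   (names are record ids).
#' @export
read_alignment <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_data("cannot parse aligned FASTA ", path, ": ",
                                  conditionMessage(e))
  )
  if (length(set) == 0L) stop_data("no sequences in ", path)
  rows <- toupper(as.character(set))
  names(rows) <- sub("[[:space:]].*$", "", names(set))
  if (any(grepl(".", rows, fixed = TRUE))) {
    stop_data("'.' gap symbol not supported; use '-' (record ",
              names(rows)[grepl(".", rows, fixed = TRUE)][[1L]], ")")
  }
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- names(rows)[lens != lens[[1L]]][[1L]]
    stop_data("ragged alignment: record ", bad, " has length ",
              nchar(rows[[bad]]), ", expected ", lens[[1L]])
  }
  rows
}

#' Write a multiple sequence alignment as aligned FASTA
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  set <- Biostrings::AAStringSet(msa)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Remove alignment columns with too many gaps
#'
#' A column is removed iff its gap fraction (gap rows / total rows) is at
#' or above `max_gap_fraction`; with the default 0.20 this drops columns
#' with >= 20% gaps.  Column order and row ids are preserved, and the
#' operation is idempotent.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param max_gap_fraction Removal threshold in (0, 1], inclusive at the
#'   threshold (default 0.20).
#' @return The trimmed alignment, same names.
#' @export
trim_gappy_columns <- function(msa, max_gap_fraction = 0.20) {
  if (!length(msa)) stop_data("empty alignment")
  if (is.na(max_gap_fraction) || max_gap_fraction <= 0 ||
      max_gap_fraction > 1) {
    stop_config("max_gap_fraction must be in (0, 1], got ", max_gap_fraction)
  }
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop_data("ragged alignment")
  if (lens[[1L]] == 0L) return(msa)
  chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-")
  keep <- gap_frac < max_gap_fraction
  out <- vapply(seq_along(msa),
                function(r) paste(chars[r, keep], collapse = ""),
                character(1))
  stats::setNames(out, names(msa))
}

#' Assign each query sequence to its nearest reference
#'
#' Each query is globally aligned to every reference and assigned to the
#' reference with the highest percent identity; ties are broken by
#' reference input order.  This is the grouping step used to organise a
#' gene family around a set of reference polypeptides.
#'
#' @param queries,references Protein-record `data.frame`s (see
#'   [read_fasta()]); at least one reference is required.
#' @param mode Identity convention, see [percent_identity()].
#' @param matrix,gap_open,gap_extend Alignment scoring, see
#'   [needleman_wunsch()].
#' @return `data.frame` with columns `query`, `reference`, `identity`
#'   (percent), one row per query in input order.
#' @export
nearest_reference_grouping <- function(queries, references,
                                       mode = c("aligned_columns",
                                                "shorter_sequence"),
                                       matrix = "BLOSUM62",
                                       gap_open = 10, gap_extend = 1) {
  mode <- match.arg(mode)
  if (is.null(references) || nrow(references) == 0L) {
    stop_config("at least one reference sequence is required")
  }
  if (is.null(queries) || nrow(queries) == 0L) {
    return(data.frame(query = character(0), reference = character(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  sub <- substitution_matrix(matrix)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    ids <- vapply(seq_len(nrow(references)), function(j) {
      aln <- needleman_wunsch(queries$residues[[i]],
                              references$residues[[j]],
                              matrix = sub, gap_open = gap_open,
                              gap_extend = gap_extend)
      percent_identity(aln, mode)
    }, numeric(1))
    best <- which.max(ids)  # first max = reference input order tie-break
    data.frame(query = queries$id[[i]], reference = references$id[[best]],
               identity = ids[[best]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
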