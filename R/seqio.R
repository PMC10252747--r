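#' Construct a set of protein records
#'
#' The package's working container for protein sequences is a plain
#' `data.frame` with columns `id`, `description` and `residues`, one row
#' per protein.  Residues are stored uppercase over the 20 standard
#' one-letter amino-acid codes plus `X` (unknown).
#'
#' @param id Character vector of unique identifiers (no whitespace).
#' @param residues Character vector of sequences (non-empty).
#' @param description Character vector of free-text descriptions
#'   (recycled; may be empty strings).
#' @return A `data.frame` with columns `id`, `description`, `residues`.
#' @examples
#' protein_records(c("a", "b"), c("PASTPA", "MGGLV"))
#' @export
protein_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  description <- rep_len(as.character(description), length(id))
  if (length(id) != length(residues)) {
    stop_config("id and residues must have equal length")
  }
  if (any(grepl("[[:space:]]", id))) {
    stop_data("record ids must not contain whitespace: ",
              paste(id[grepl("[[:space:]]", id)], collapse = ", "))
  }
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop_data("duplicate record id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(residues))) {
    stop_data("empty sequence for record(s): ",
              paste(id[!nzchar(residues)], collapse = ", "))
  }
  bad <- check_alphabet(residues)
  if (!is.null(bad)) {
    stop_data("illegal residue '", bad$char, "' in record ", id[bad$row],
              " at position ", bad$pos)
  }
  data.frame(id = id, description = description, residues = residues,
             stringsAsFactors = FALSE)
}

# First offending character outside [AA_STANDARD, X], or NULL.
check_alphabet <- function(residues) {
  pat <- paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]")
  hit <- regexpr(pat, residues)
  row <- which(hit > 0L)
  if (!length(row)) return(NULL)
  row <- row[[1L]]
  pos <- hit[[row]]
  list(row = row, pos = pos, char = substr(residues[[row]], pos, pos))
}

#' Read a protein multi-FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; this wrapper
#' adds the validation the screen relies on: unique whitespace-free ids,
#' canonical uppercase residues, and a strict alphabet of the 20 standard
#' amino acids plus `X`.  Lowercase input is canonicalised to uppercase.
#'
#' @param path Path to a FASTA file.
#' @param on_illegal What to do with characters outside the alphabet:
#'   `"error"` (default) aborts naming the record and position; `"mask"`
#'   replaces them with `X`.
#' @return A protein-record `data.frame` (see [protein_records()]), rows
#'   in file order.
#' @export
read_fasta <- function(path, on_illegal = c("error", "mask")) {
  on_illegal <- match.arg(on_illegal)
  if (!file.exists(path)) stop_data("file not found: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_data("cannot parse FASTA ", path, ": ",
                                  conditionMessage(e))
  )
  if (length(set) == 0L) stop_data("no sequences in ", path)
  headers <- names(set)
  id <- sub("[[:space:]].*$", "", headers)
  description <- ifelse(grepl("[[:space:]]", headers),
                        sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  residues <- toupper(as.character(set))
  if (on_illegal == "mask") {
    pat <- paste0("[^", paste(c(AA_STANDARD, "X"), collapse = ""), "]")
    residues <- gsub(pat, "X", residues)
  }
  protein_records(id, residues, description)
}

#' Write protein records as FASTA
#'
#' Sequences are wrapped at 60 columns.  Descriptions, when present, are
#' appended to the id on the header line after a single space.
#'
#' @param records A protein-record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description), records$id)
  set <- Biostrings::AAStringSet(stats::setNames(records$residues, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# Fixed column order of the classification report.
REPORT_COLUMNS <- c(
  "id", "length", "sp_present", "sp_cleavage",
  "past_percent_full", "past_percent_mature",
  "repeat_count", "repeat_density", "repeat_span",
  "verdict", "reasons"
)

#' Write a classification report as TSV
#'
#' One row per protein, fixed header, tab-separated.  Percentages are
#' rounded to 1 decimal, repeat density to 2 and repeat span to 3 at
#' report time only; upstream computation keeps full precision.
#'
#' @param classifications Result `data.frame` from [scan_proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(classifications, path) {
  df <- classifications
  out <- data.frame(
    id = df$id,
    length = df$length,
    sp_present = ifelse(df$sp_present, "1", "0"),
    sp_cleavage = ifelse(is.na(df$sp_cleavage), "NA",
                         format(df$sp_cleavage, trim = TRUE)),
    past_percent_full = sprintf("%.1f", df$past_percent_full),
    past_percent_mature = sprintf("%.1f", df$past_percent_mature),
    repeat_count = df$repeat_count,
    repeat_density = sprintf("%.2f", df$repeat_density),
    repeat_span = sprintf("%.3f", df$repeat_span),
    verdict = df$verdict,
    reasons = df$reasons,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wb")  # fixed EOLs -> byte-identical reruns
  on.exit(close(con))
  writeLines(paste(REPORT_COLUMNS, collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a classification report
#'
#' @param path Path to a TSV written by [write_report()].
#' @return `data.frame` with typed columns (`sp_present` logical,
#'   percentages numeric, `sp_cleavage` integer with `NA` for absent).
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), REPORT_COLUMNS)) {
    stop_data("unexpected report header in ", path)
  }
  data.frame(
    id = df$id,
    length = as.integer(df$length),
    sp_present = df$sp_present == "1",
    sp_cleavage = suppressWarnings(as.integer(df$sp_cleavage)),
    past_percent_full = as.numeric(df$past_percent_full),
    past_percent_mature = as.numeric(df$past_percent_mature),
    repeat_count = as.integer(df$repeat_count),
    repeat_density = as.numeric(df$repeat_density),
    repeat_span = as.numeric(df$repeat_span),
    verdict = df$verdict,
    reasons = df$reasons,
    stringsAsFactors = FALSE
  )
}
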