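# Repertoire I/O. Records travel as AIRR-style Rearrangement TSV (amino-acid
# level) with one non-standard column, cell_subtype, carrying the weak
# supervision label, plus optional cdr3 span and mutation-count columns.
# Coordinates are 1-based inclusive on disk (AIRR convention) and 0-based
# half-open in memory; conversion happens only here.

AIRR_REQUIRED <- c("sequence_id", "sequence_alignment_aa", "v_call", "j_call",
                   "locus")

#' Write records as AIRR-style Rearrangement TSV
#'
#' @param records data.frame of BCR records (see [simulate_record()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  df <- data.frame(
    sequence_id = records$id,
    sequence_alignment_aa = records$sequence,
    junction_aa = records$hcdr3,
    v_call = records$v_call,
    d_call = records$d_call,
    j_call = records$j_call,
    c_call = records$isotype,
    locus = records$locus,
    cell_subtype = records$subtype,
    cdr3_start = if (!is.null(records$hcdr3_start)) records$hcdr3_start + 1L else NA,
    cdr3_end = records$hcdr3_end,
    n_mutations = records$n_mutations,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AIRR-style Rearrangement TSV
#'
#' Requires columns sequence_id, sequence_alignment_aa, v_call, j_call and
#' locus; optional
#' columns (junction_aa, d_call, c_call, cell_subtype, cdr3_start, cdr3_end,
#' n_mutations) are marked absent (`NA`) when missing. 1-based inclusive
#' coordinates are converted to internal 0-based half-open spans.
#'
#' @param path TSV file.
#' @return data.frame of BCR records.
#' @export
read_airr <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing_cols) > 0) {
    stop("AIRR file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty AIRR file: ", path)
  }
  opt <- function(col, default = NA) {
    if (col %in% names(df)) df[[col]] else rep(default, nrow(df))
  }
  out <- data.frame(
    id = as.character(df$sequence_id),
    chain = ifelse(df$locus == "IGH", "heavy", "light"),
    locus = df$locus,
    sequence = df$sequence_alignment_aa,
    hcdr3 = as.character(opt("junction_aa", NA_character_)),
    hcdr3_start = suppressWarnings(as.integer(opt("cdr3_start"))) - 1L,
    hcdr3_end = suppressWarnings(as.integer(opt("cdr3_end"))),
    v_call = df$v_call,
    d_call = as.character(opt("d_call", NA_character_)),
    j_call = df$j_call,
    isotype = as.character(opt("c_call", NA_character_)),
    subtype = as.character(opt("cell_subtype", NA_character_)),
    n_mutations = suppressWarnings(as.integer(opt("n_mutations"))),
    stringsAsFactors = FALSE
  )
  out
}

#' Write records as FASTA
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  xs <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a FASTA file of amino-acid sequences
#'
#' Minimal ingest path: ids and sequences only; all annotation fields absent.
#'
#' @param path FASTA file.
#' @return data.frame of BCR records with annotation columns `NA`.
#' @export
read_fasta_records <- function(path) {
  xs <- Biostrings::readAAStringSet(path)
  data.frame(id = names(xs), chain = NA_character_, locus = NA_character_,
             sequence = as.character(xs), hcdr3 = NA_character_,
             hcdr3_start = NA_integer_, hcdr3_end = NA_integer_,
             v_call = NA_character_, d_call = NA_character_,
             j_call = NA_character_, isotype = NA_character_,
             subtype = NA_character_, n_mutations = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Write a paratope label table
#'
#' @param records data.frame from [simulate_paratope_set()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_paratope_tsv <- function(records, path) {
  write.table(records[c("id", "chain", "sequence", "labels")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paratope label table
#'
#' @param path TSV with columns id, chain, sequence, labels.
#' @return data.frame; errors if any label string length differs from its
#'   sequence length or contains characters other than 0/1.
#' @export
read_paratope_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(labels = "character"))
  bad <- nchar(df$labels) != nchar(df$sequence) | grepl("[^01]", df$labels)
  if (any(bad)) {
    stop("malformed paratope labels for record(s): ",
         paste(head(df$id[bad]), collapse = ", "), call. = FALSE)
  }
  df
}

#' @noRd
label_matrix_from_strings <- function(labels) {
  lapply(strsplit(labels, ""), function(x) as.integer(x))
}
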