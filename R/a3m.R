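#' Multiple sequence alignments with A3M semantics
#'
#' An `msa` holds one aligned string per record.  Uppercase letters and `-`
#' occupy match columns (defined by the first record, normally the cluster
#' representative or consensus); lowercase letters are insertions relative to
#' the match states and do not occupy columns.  All records span the same
#' number of match columns.
#'
#' @param accession Character vector of record identifiers.
#' @param aligned Parallel character vector of A3M-encoded rows.
#' @return An object of class `msa` with fields `accession`, `aligned` and
#'   `n_match_columns`.
#' @export
msa <- function(accession, aligned) {
  stopifnot(length(accession) == length(aligned), length(accession) >= 1)
  nm <- n_match_cols(aligned)
  if (length(unique(nm)) != 1L)
    abort(sprintf("inconsistent match-column counts: %s",
                  paste(unique(nm), collapse = ", ")))
  structure(list(accession = as.character(accession),
                 aligned = as.character(aligned),
                 n_match_columns = nm[1]),
            class = "msa")
}

n_match_cols <- function(aligned) {
  nchar(gsub("[a-z]", "", aligned))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d records, %d match columns\n",
              length(x$accession), x$n_match_columns))
  invisible(x)
}

#' @export
length.msa <- function(x) length(x$accession)

# Match-state characters of each record as an n_records x n_match_columns
# character matrix ('-' for deletions; insertions dropped).  The workhorse
# view for consensus, profiles, diversity filtering and annotation transfer.
msa_match_matrix <- function(m) {
  rows <- strsplit(gsub("[a-z]", "", m$aligned), "")
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
         dimnames = list(m$accession, NULL))
}

# For one record: residue index within the (ungapped) member sequence at each
# match column, NA where the member has a deletion.  Lowercase insertions
# advance the residue index without occupying a column.
msa_residue_index <- function(m, record) {
  chars <- strsplit(m$aligned[record], "")[[1]]
  is_ins <- grepl("[a-z]", chars)
  is_res <- chars != "-"
  idx <- cumsum(is_res)
  out <- ifelse(is_res, idx, NA_integer_)[!is_ins]
  as.integer(out)
}

#' Read and write A3M alignment files
#'
#' FASTA-like on disk: a header line per record, aligned strings with A3M
#' semantics as the body.  The round trip is lossless.
#'
#' @param path File path.
#' @param m An `msa`.
#' @export
parse_a3m <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1]) abort(sprintf("'%s' is not A3M", path))
  idx <- cumsum(hdr)
  aligned <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  msa(sub("\\s.*$", "", sub("^>", "", lines[hdr])), unname(aligned))
}

#' @rdname parse_a3m
#' @export
write_a3m <- function(m, path) {
  writeLines(paste0(">", m$accession, "\n", m$aligned), path)
  invisible(path)
}
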