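#' Domain annotation tables
#'
#' One row per database match: identifiers for query and target, 1-based
#' inclusive start/end and total length on both sides, and the match E-value
#' — the nine columns of the standard annotation exchange format.  The
#' `database` label (pfam/scop/pdb) is carried as a column in memory and as
#' one file per database on disk.
#'
#' @param query_id,target_id Identifiers.
#' @param q_start,q_end,q_len,t_start,t_end,t_len 1-based inclusive
#'   coordinates and total lengths.
#' @param evalue Positive E-values.
#' @param database `"pfam"`, `"scop"` or `"pdb"`.
#' @return A tibble with the nine columns plus `database`.
#' @export
annotation_tbl <- function(query_id, target_id, q_start, q_end, q_len,
                           t_start, t_end, t_len, evalue, database = "pfam") {
  tbl <- tibble(query_id = as.character(query_id),
                target_id = as.character(target_id),
                q_start = as.integer(q_start), q_end = as.integer(q_end),
                q_len = as.integer(q_len),
                t_start = as.integer(t_start), t_end = as.integer(t_end),
                t_len = as.integer(t_len),
                evalue = as.numeric(evalue),
                database = rep_len(as.character(database), length(query_id)))
  validate_annotations(tbl)
}

validate_annotations <- function(tbl) {
  ok <- tbl$q_start >= 1 & tbl$q_start <= tbl$q_end & tbl$q_end <= tbl$q_len &
    tbl$t_start >= 1 & tbl$t_start <= tbl$t_end & tbl$t_end <= tbl$t_len &
    tbl$evalue > 0
  if (!all(ok))
    abort(sprintf("invalid annotation record (row %d): coordinates must satisfy 1 <= start <= end <= len and evalue > 0",
                  which(!ok)[1]))
  if (!all(tbl$database %in% c("pfam", "scop", "pdb")))
    abort("database must be one of pfam, scop, pdb")
  tbl
}

#' Write and read the nine-column annotation TSV
#'
#' Columns, in order: query identifier, target identifier, query start, end
#' and total length, target start, end and total length, E-value.
#'
#' @param annots An annotation tibble (see [annotation_tbl()]).
#' @param path File path.
#' @param database Database label attached to all records on read.
#' @export
write_annotation_tsv <- function(annots, path) {
  validate_annotations(annots)
  cols <- c("query_id", "target_id", "q_start", "q_end", "q_len",
            "t_start", "t_end", "t_len", "evalue")
  readr::write_tsv(as_tibble(annots)[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path, database = "pfam") {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) &&
      any(lengths(strsplit(raw, "\t", fixed = TRUE)) != 9L))
    abort("annotation TSV lines must have exactly nine tab-separated fields")
  if (!length(raw)) {
    return(annotation_tbl(character(), character(), integer(), integer(),
                          integer(), integer(), integer(), integer(),
                          numeric(), character()))
  }
  tbl <- readr::read_tsv(path, col_names = c("query_id", "target_id",
                                             "q_start", "q_end", "q_len",
                                             "t_start", "t_end", "t_len",
                                             "evalue"),
                         col_types = "cciiiiiid", progress = FALSE)
  tbl$database <- database
  validate_annotations(tbl)
}
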