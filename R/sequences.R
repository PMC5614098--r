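#' Build a validated protein sequence table
#'
#' The central data container of the package: one row per protein, with the
#' residue string and optional functional annotation columns.  All
#' user-facing functions take and return this shape, so calls chain with the
#' pipe.
#'
#' @param accession Character vector of unique identifiers.
#' @param residues Character vector of amino-acid strings (20 standard
#'   letters plus X after normalization).
#' @param description Free-text protein description lines.
#' @param source `"reviewed"` (Swiss-Prot-like, takes precedence in header
#'   summaries) or `"unreviewed"`.
#' @param keywords,go_terms List columns of character vectors (annotation
#'   sets per protein).
#' @param name Recommended protein name.
#' @return A tibble with columns `accession`, `residues`, `description`,
#'   `source`, `keywords`, `go_terms`, `name`.
#' @export
protein_tbl <- function(accession, residues, description = "",
                        source = "unreviewed", keywords = NULL,
                        go_terms = NULL, name = NA_character_) {
  n <- length(accession)
  tbl <- tibble(
    accession = as.character(accession),
    residues = normalize_residues(residues, accession),
    description = rep_len(as.character(description), n),
    source = rep_len(as.character(source), n),
    keywords = keywords %||% rep_len(list(character()), n),
    go_terms = go_terms %||% rep_len(list(character()), n),
    name = rep_len(as.character(name), n)
  )
  validate_proteins(tbl)
}

validate_proteins <- function(tbl) {
  if (anyDuplicated(tbl$accession)) {
    dup <- unique(tbl$accession[duplicated(tbl$accession)])
    abort(sprintf("duplicate accession(s): %s",
                  paste(head(dup, 5), collapse = ", ")))
  }
  if (any(!nzchar(tbl$residues)))
    abort(sprintf("empty residue string for accession %s",
                  tbl$accession[!nzchar(tbl$residues)][1]))
  bad <- !tbl$source %in% c("reviewed", "unreviewed")
  if (any(bad)) abort("source must be 'reviewed' or 'unreviewed'")
  tbl
}

# Uppercase; map ambiguity/rare codes U,O,B,Z,J to X (with a warning); reject
# anything outside the amino-acid alphabet, '*' and gaps included.
normalize_residues <- function(residues, accession = seq_along(residues)) {
  residues <- toupper(as.character(residues))
  mapped <- chartr("UOBZJ", "XXXXX", residues)
  if (any(mapped != residues))
    warn("non-standard residues (U/O/B/Z/J) mapped to X")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", mapped)
  if (!all(ok)) {
    i <- which(!ok)[1]
    offending <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", mapped[i])
    abort(sprintf("record '%s' contains invalid character(s): %s",
                  accession[i], substr(offending, 1, 5)))
  }
  mapped
}

#' Read and write FASTA files with UniProt-style headers
#'
#' `parse_fasta()` reads a FASTA file into a protein table: the accession is
#' the first whitespace-delimited token after `>`, the remainder of the
#' header line becomes the description.  A `source` of `"reviewed"` is
#' inferred from headers starting with `sp|`.  `write_fasta()` is its
#' inverse.
#'
#' @param path File path.
#' @param wrap Line width for sequence wrapping on write (0 = no wrapping).
#' @return `parse_fasta()` returns a protein tibble (see [protein_tbl()]).
#' @export
parse_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1])
    abort(sprintf("'%s' is not FASTA: no header line", path))
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  if (length(seqs) < sum(hdr)) {
    # records with no sequence lines
    missing <- setdiff(as.character(seq_len(sum(hdr))), names(seqs))
    seqs[missing] <- ""
    seqs <- seqs[order(as.integer(names(seqs)))]
  }
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (any(grepl("[*.-]", seqs))) {
    i <- which(grepl("[*.-]", seqs))[1]
    abort(sprintf("record '%s' contains '*' or gap characters", accession[i]))
  }
  source <- ifelse(grepl("^sp\\|", accession), "reviewed", "unreviewed")
  protein_tbl(accession, seqs, description, source)
}

#' @rdname parse_fasta
#' @param seqs A protein tibble.
#' @export
write_fasta <- function(seqs, path, wrap = 60) {
  hdr <- paste0(">", seqs$accession,
                ifelse(nzchar(seqs$description), paste0(" ", seqs$description), ""))
  body <- if (wrap > 0) {
    vapply(seqs$residues, function(s) {
      paste(substring(s, seq(1, nchar(s), wrap),
                      pmin(seq(1, nchar(s), wrap) + wrap - 1, nchar(s))),
            collapse = "\n")
    }, "", USE.NAMES = FALSE)
  } else seqs$residues
  writeLines(paste0(hdr, "\n", body), path)
  invisible(path)
}

#' Split over-long sequences into near-equal pieces
#'
#' Sequences longer than `max_len` residues (14 000 by default) are split
#' into `ceiling(L / max_len)` near-equal pieces to bound memory use and keep
#' downstream tools happy.  Pieces get suffixed accessions `acc_1`, `acc_2`,
#' ... in order, so concatenating them reconstructs the original; sequences
#' at or below the threshold pass through unchanged.
#'
#' @param seqs A protein tibble.
#' @param max_len Maximum residue length retained as a single entry.
#' @return A protein tibble in which every sequence has length `<= max_len`.
#' @export
split_long_sequences <- function(seqs, max_len = 14000) {
  stopifnot(max_len >= 1)
  if (!nrow(seqs)) return(seqs)
  lens <- nchar(seqs$residues)
  if (all(lens <= max_len)) return(seqs)
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    L <- lens[i]
    if (L <= max_len) return(seqs[i, ])
    k <- ceiling(L / max_len)
    bounds <- round(seq(0, L, length.out = k + 1))
    piece <- substring(seqs$residues[i], bounds[-(k + 1)] + 1, bounds[-1])
    out <- seqs[rep(i, k), ]
    out$accession <- paste0(seqs$accession[i], "_", seq_len(k))
    out$residues <- piece
    out
  })
  validate_proteins(dplyr::bind_rows(rows))
}
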