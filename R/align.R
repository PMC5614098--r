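# residue string -> integer codes into the matrix alphabet (1-based)
seq_codes <- function(residues, m = blosum62()) {
  codes <- match(strsplit(residues, "")[[1]], m$alphabet)
  if (anyNA(codes)) abort("residue outside the scoring alphabet")
  codes
}

# Full local alignment including the traceback path; every DP call in the
# package funnels through here so alignment_count() stays meaningful.
align_path <- function(q_res, t_res, m = blosum62()) {
  qc <- seq_codes(q_res, m)
  tc <- seq_codes(t_res, m)
  S <- m$scores[qc, tc, drop = FALSE]
  the$n_alignments <- the$n_alignments + 1L
  res <- sw_dp(S, qc, tc, m$gap_open, m$gap_extend)
  res$q_len <- length(qc)
  res$t_len <- length(tc)
  res
}

#' Pairwise local alignment
#'
#' Smith-Waterman local alignment with affine gap penalties under the given
#' substitution matrix (BLOSUM62 11/1 by default).  The traceback is
#' deterministic: among equal-scoring cells the one with the smallest query
#' then target position starts the traceback, and score ties during
#' traceback are resolved diagonal > up > left.  Identity is the fraction of
#' aligned (residue-vs-residue) columns with identical residues; coverage is
#' the aligned span length over the full sequence length, per sequence.
#'
#' @param q,t Query and target: single-row protein tibbles, or plain residue
#'   strings.
#' @param m A [substitution_matrix][read_score_matrix].
#' @param q_id,t_id Identifiers used when `q`/`t` are plain strings.
#' @return A one-row tibble: `q_id`, `t_id`, `score`, `n_identical`,
#'   `n_aligned_cols`, `identity`, `q_cov`, `t_cov`, `score_per_res`, and the
#'   1-based aligned spans `q_start`, `q_end`, `t_start`, `t_end`.
#' @examples
#' align_pair("ACDEFGHIKL", "ACDEFGHIKV")
#' @export
align_pair <- function(q, t, m = blosum62(), q_id = "query", t_id = "target") {
  if (is.data.frame(q)) { q_id <- q$accession[1]; q <- q$residues[1] }
  if (is.data.frame(t)) { t_id <- t$accession[1]; t <- t$residues[1] }
  if (!nzchar(q) || !nzchar(t)) abort("sequences must be non-empty")
  p <- align_path(q, t, m)
  alignment_row(p, q_id, t_id)
}

alignment_row <- function(p, q_id, t_id) {
  n_al <- p$n_aligned_cols
  tibble(
    q_id = q_id, t_id = t_id, score = p$score,
    n_identical = p$n_identical, n_aligned_cols = n_al,
    identity = if (n_al > 0) p$n_identical / n_al else 0,
    q_cov = if (n_al > 0) (p$q_end - p$q_start + 1) / p$q_len else 0,
    t_cov = if (n_al > 0) (p$t_end - p$t_start + 1) / p$t_len else 0,
    score_per_res = if (n_al > 0) p$score / n_al else -Inf,
    q_start = p$q_start, q_end = p$q_end,
    t_start = p$t_start, t_end = p$t_end,
    q_len = p$q_len, t_len = p$t_len
  )
}

#' Reduce sequences to a five-letter alphabet
#'
#' Many-to-one physicochemical partition of the amino acids into five
#' classes, used for fast redundancy hashing: tiny-polar \{A,S,T,G,P\} -> A,
#' cysteine \{C\} -> C, charged-polar/acid/amide \{D,E,N,Q,X\} -> D, basic
#' \{K,R,H\} -> K, hydrophobic \{M,I,L,V,F,Y,W\} -> M.  Length is preserved.
#'
#' @param residues Character vector of residue strings.
#' @return Character vector over the letters A, C, D, K, M.
#' @export
reduce_alphabet <- function(residues) {
  chartr("ASTGPCDENQXKRHMILVFYW",
         "AAAAACDDDDDKKKMMMMMMM", toupper(residues))
}

#' Deterministic 64-bit sequence hash
#'
#' FNV-1a hash of a string, returned as a 16-character lowercase hex string
#' (R lacks an unsigned 64-bit type).  Stable across runs and platforms;
#' collisions are never trusted — hash buckets are always verified by exact
#' residue comparison before any merge.
#'
#' @param x Character vector.
#' @return Character vector of 16-hex-digit hashes.
#' @export
hash64 <- function(x) fnv1a64(x)
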