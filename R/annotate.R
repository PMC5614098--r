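#' Parameters of annotation acceptance and transfer
#'
#' @param K,lambda Karlin-Altschul parameters of the subalignment E-value
#'   term (defaults 0.041 and 0.267, the standard gapped-BLOSUM62
#'   constants).
#' @param evalue_cutoff Acceptance/transfer E-value threshold (default
#'   0.01).
#' @param max_overlap_frac Maximum fraction of a candidate match's own query
#'   span that may overlap already-accepted annotations (default 0.10).
#' @param literal If `TRUE`, use the exponential term `exp(+lambda * s)`.
#'   With that sign the term grows with subalignment quality, so good
#'   subalignments fail the cutoff; the default `FALSE` uses
#'   `exp(-lambda * s)`, under which the E-value decreases as the member
#'   region becomes more clearly homologous to the consensus.  The flag
#'   exists for auditing only.
#' @return A list of class `transfer_params`.
#' @export
transfer_params <- function(K = 0.041, lambda = 0.267, evalue_cutoff = 0.01,
                            max_overlap_frac = 0.10, literal = FALSE) {
  stopifnot(K > 0, lambda > 0, evalue_cutoff > 0,
            max_overlap_frac > 0, max_overlap_frac < 1)
  structure(list(K = K, lambda = lambda, evalue_cutoff = evalue_cutoff,
                 max_overlap_frac = max_overlap_frac, literal = literal),
            class = "transfer_params")
}

#' Accept non-overlapping domain matches for one query
#'
#' Processes matches of one query against one database in order of
#' increasing E-value (ties: longer query span, then target identifier) and
#' accepts a match iff its E-value is below `evalue_cutoff` and its query
#' span overlaps the union of already-accepted spans by less than
#' `max_overlap_frac` of its own length.  Matches to different databases
#' should be filtered in separate calls so that a region may carry one
#' annotation per database.
#'
#' @param matches Annotation tibble ([annotation_tbl()]) sharing one
#'   `query_id` and one `database`.
#' @param params A [transfer_params()].
#' @return The accepted subset, in acceptance order.
#' @export
accept_annotations <- function(matches, params = transfer_params()) {
  if (!nrow(matches)) return(matches)
  if (length(unique(matches$query_id)) != 1L)
    abort("all matches must share one query_id")
  if (length(unique(matches$database)) != 1L)
    abort("all matches must come from one database")
  validate_annotations(matches)
  span <- matches$q_end - matches$q_start + 1L
  ord <- order(matches$evalue, -span, matches$target_id)
  covered <- rep(FALSE, matches$q_len[1])
  accept <- integer()
  for (i in ord) {
    if (matches$evalue[i] >= params$evalue_cutoff) next
    idx <- seq(matches$q_start[i], matches$q_end[i])
    if (sum(covered[idx]) / length(idx) < params$max_overlap_frac) {
      accept <- c(accept, i)
      covered[idx] <- TRUE
    }
  }
  matches[accept, ]
}

#' Subalignment E-value for annotation transfer
#'
#' `E_subali = E_domain + K * length_consensus * exp(-lambda * s_subali)`:
#' the domain match E-value plus a Karlin-Altschul term measuring how likely
#' a subalignment of score `s_subali` between the cluster consensus and a
#' member sequence is by chance.  Strictly decreasing in `s_subali`,
#' strictly increasing in `e_domain` and `length_consensus`, and never below
#' `e_domain`.
#'
#' @param e_domain Domain match E-value (positive).
#' @param s_subali Substitution score of the member-vs-consensus
#'   subalignment over the annotated span.
#' @param length_consensus Consensus sequence length (>= 1).
#' @param params A [transfer_params()].
#' @return The subalignment E-value (vectorized).
#' @export
subalignment_evalue <- function(e_domain, s_subali, length_consensus,
                                params = transfer_params()) {
  stopifnot(all(length_consensus >= 1), all(e_domain > 0))
  sgn <- if (isTRUE(params$literal)) 1 else -1
  e_domain + params$K * length_consensus * exp(sgn * params$lambda * s_subali)
}

#' Transfer cluster annotations to member sequences
#'
#' For every member of the cluster MSA and every accepted cluster-level
#' annotation, the member-vs-consensus subalignment score over the annotated
#' consensus span is read off the MSA match columns (deletion columns are
#' unscored; a member with no residue in the span has no homologous region
#' and receives nothing).  The annotation is transferred iff its
#' [subalignment_evalue()] is below the cutoff; transferred coordinates are
#' mapped through the MSA onto the member sequence and the reported E-value
#' is the subalignment E-value.
#'
#' @param cluster_annots Accepted annotations on the cluster consensus
#'   (query coordinates in consensus/match-column space).
#' @param m The cluster [msa].
#' @param consensus The cluster `consensus_record` (or string).
#' @param members Protein tibble giving full member lengths.
#' @param matrix Substitution matrix.
#' @param params A [transfer_params()].
#' @return Annotation tibble with one row per transferred (member,
#'   annotation) pair.
#' @export
transfer_annotations <- function(cluster_annots, m, consensus, members,
                                 matrix = blosum62(),
                                 params = transfer_params()) {
  cons <- strsplit(consensus_seq(consensus), "")[[1]]
  L <- length(cons)
  if (L != m$n_match_columns)
    abort("consensus length must equal the MSA's match-column count")
  if (nrow(cluster_annots) &&
      any(cluster_annots$q_end > L | cluster_annots$q_start < 1))
    abort("annotation span outside the consensus")
  M <- msa_match_matrix(m)
  full_len <- setNames(nchar(members$residues), members$accession)
  out <- list()
  for (i in seq_along(m$accession)) {
    acc <- m$accession[i]
    ridx <- msa_residue_index(m, i)
    for (k in seq_len(nrow(cluster_annots))) {
      span <- seq(cluster_annots$q_start[k], cluster_annots$q_end[k])
      obs <- span[M[i, span] != "-"]
      if (!length(obs)) next
      s_sub <- sum(matrix$scores[cbind(M[i, obs], cons[obs])])
      e_sub <- subalignment_evalue(cluster_annots$evalue[k], s_sub, L, params)
      if (e_sub >= params$evalue_cutoff) next
      row <- cluster_annots[k, ]
      row$query_id <- acc
      row$q_start <- min(ridx[obs])
      row$q_end <- max(ridx[obs])
      row$q_len <- unname(full_len[acc])
      row$evalue <- e_sub
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(cluster_annots[0, ])
  validate_annotations(dplyr::bind_rows(out))
}
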