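#' Build a per-cluster multiple sequence alignment
#'
#' Center-star MSA around the cluster representative: each member's pairwise
#' local alignment to the representative is merged into one A3M alignment in
#' which the representative's positions define the match columns.  Member
#' residues aligned to representative positions are uppercase, deleted
#' representative positions are `-`, and member residues falling between
#' representative positions become lowercase insertions.  Because every
#' member already satisfies identity and coverage thresholds to its
#' representative, the star topology loses essentially nothing relative to a
#' full progressive alignment at these identity levels.
#'
#' @param members Protein tibble of cluster members.
#' @param representative Accession of the representative (must be a member).
#' @param m Substitution matrix.
#' @return An [msa] whose first record is the representative;
#'   `n_match_columns` equals the representative length.
#' @export
build_msa <- function(members, representative, m = blosum62()) {
  if (!nrow(members)) abort("empty member list")
  if (!representative %in% members$accession)
    abort("representative must be one of the members")
  rep_res <- members$residues[members$accession == representative]
  L <- nchar(rep_res)
  others <- members[members$accession != representative, ]
  rows <- vapply(seq_len(nrow(others)), function(i) {
    a3m_row(others$residues[i], rep_res, L, m)
  }, "")
  msa(c(representative, others$accession), c(rep_res, rows))
}

# one member row in A3M coordinates relative to the representative
a3m_row <- function(mem_res, rep_res, L, m) {
  p <- align_path(mem_res, rep_res, m)
  cols <- rep("-", L)
  ins <- rep("", L + 1)  # insertions after column k (k = 0 is a prefix)
  mem_chars <- strsplit(mem_res, "")[[1]]
  last_t <- max(0L, p$t_start - 1L)
  steps <- length(p$path_q)
  for (k in seq_len(steps)) {
    qi <- p$path_q[k]; tj <- p$path_t[k]
    if (qi > 0 && tj > 0) {
      cols[tj] <- mem_chars[qi]
      last_t <- tj
    } else if (tj > 0) {
      last_t <- tj
    } else {
      ins[last_t + 1L] <- paste0(ins[last_t + 1L], tolower(mem_chars[qi]))
    }
  }
  paste0(ins[1L], paste0(cols, ins[-1L], collapse = ""))
}

# per-record weights that collapse duplicate rows, normalized to sum 1
msa_weights <- function(m) {
  mult <- table(m$aligned)[m$aligned]
  w <- 1 / as.numeric(mult)
  w / sum(w)
}

consensus_seq <- function(x) {
  if (inherits(x, "consensus_record")) x$sequence else as.character(x)
}

#' Compute a cluster consensus sequence
#'
#' Per match column, the consensus residue maximizes the pseudocount-smoothed
#' profile probability.  Observed (duplicate-collapsed, weighted) residue
#' frequencies are mixed with substitution-matrix pseudocounts — the
#' BLOSUM62-derived conditional exchange probabilities of the observed
#' residues — with mixing weight `alpha`.  Ties break to the residue with
#' the higher matrix self-score, then alphabetically.
#'
#' @param m An [msa].
#' @param matrix Substitution matrix.
#' @param alpha Pseudocount admixture weight (counts-equivalent).
#' @return An object of class `consensus_record` with fields `sequence` and
#'   `accession`.
#' @export
compute_consensus <- function(m, matrix = blosum62(), alpha = 1.0) {
  M <- msa_match_matrix(m)
  # raw (unweighted) counts: the consensus reflects the column majority
  w <- rep(1 / length(m$accession), length(m$accession))
  aa <- names(aa_background())
  xp <- exchange_probs(matrix)
  self <- diag(matrix$scores[aa, aa])
  cons <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    obs <- col %in% aa
    if (!any(obs)) return("X")
    f <- vapply(aa, function(a) sum(w[obs & col == a]), numeric(1))
    f <- f / sum(f)
    n_eff <- sum(obs)
    g <- as.numeric(xp %*% f)
    p <- (n_eff * f + alpha * g) / (n_eff + alpha)
    ord <- order(-p, -self, aa)
    aa[ord[1]]
  }, "")
  structure(list(sequence = paste0(cons, collapse = ""),
                 accession = paste0(m$accession[1], "_consensus")),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus_record> %s (%d residues)\n", x$accession,
              nchar(x$sequence)))
  invisible(x)
}

#' Summarize cluster annotations into a consensus header
#'
#' Builds the header line of a cluster's consensus sequence: the cluster
#' identifier, the representative accession, the cluster size, the top five
#' non-redundant member descriptions, and all member accessions, separated
#' by `|`.  Descriptions are ranked reviewed-before-unreviewed, informative
#' before blacklisted (descriptions containing *hypothetical*, *unknown*,
#' *uncharacterized* or *putative* rank last), then by frequency and
#' alphabetically.
#'
#' @param members Protein tibble of cluster members.
#' @param cluster_id Cluster identifier string.
#' @param representative Representative accession.
#' @return A single header string (without the leading `>`).
#' @export
summarize_headers <- function(members, cluster_id, representative) {
  if (!nrow(members)) abort("empty member list")
  blacklist <- c("hypothetical", "unknown", "uncharacterized", "putative")
  d <- members[nzchar(members$description), ]
  descs <- character()
  if (nrow(d)) {
    stats <- dplyr::summarise(
      dplyr::group_by(d, .data$description),
      reviewed = any(.data$source == "reviewed"),
      freq = dplyr::n(), .groups = "drop")
    stats$black <- vapply(tolower(stats$description), function(x)
      any(vapply(blacklist, grepl, logical(1), x = x, fixed = TRUE)),
      logical(1))
    stats <- stats[order(-stats$reviewed, stats$black, -stats$freq,
                         stats$description), ]
    descs <- head(stats$description, 5L)
  }
  paste(cluster_id, representative, sprintf("n=%d", nrow(members)),
        paste(descs, collapse = "; "),
        paste(members$accession, collapse = ","), sep = "|")
}

#' Build a position-specific scoring matrix from an MSA
#'
#' Per-column profile scores obtained as the duplicate-collapsed,
#' weight-averaged substitution-matrix rows of the observed residues: each
#' observed residue contributes its full matrix row, which acts as the
#' pseudocount prior, so scores are finite for all residues even when
#' unobserved and a single-sequence MSA reproduces exactly that sequence's
#' matrix rows.
#'
#' @param m An [msa].
#' @param matrix Substitution matrix.
#' @return An object of class `pssm`: `n_cols`, `scores` (residues x
#'   columns, rows = 20 amino acids plus X), and the `consensus` string.
#' @export
build_pssm <- function(m, matrix = blosum62()) {
  M <- msa_match_matrix(m)
  w <- msa_weights(m)
  letters21 <- c(names(aa_background()), "X")
  sc <- matrix$scores[letters21, letters21]
  scores <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[, j]
    obs <- col %in% letters21
    if (!any(obs)) return(sc[, "X"])
    f <- vapply(letters21, function(a) sum(w[obs & col == a]), numeric(1))
    as.numeric(sc %*% (f / sum(f)))
  }, numeric(length(letters21)))
  rownames(scores) <- letters21
  structure(list(n_cols = ncol(M), scores = scores,
                 consensus = consensus_seq(compute_consensus(m, matrix))),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d columns\n", x$n_cols))
  invisible(x)
}

#' Parameters of the MSA diversification (boost) stage
#'
#' @param n_iterations Number of profile-search iterations (default 4).
#' @param filter_min_score_per_res Diversity filter threshold: minimum
#'   substitution score per aligned residue to the consensus.  The published
#'   diversity tiers use 0.0, 0.5 and 1.1 (heuristically matching 10%, 20%
#'   and 30% sequence identity).
#' @param search_evalue_cutoff E-value cutoff of the profile search.
#' @param K,lambda Karlin-Altschul parameters of the E-value computation.
#' @return A list of class `boost_params`.
#' @export
boost_params <- function(n_iterations = 4, filter_min_score_per_res = 0.0,
                         search_evalue_cutoff = 1e-3, K = 0.041,
                         lambda = 0.267) {
  stopifnot(n_iterations >= 1, search_evalue_cutoff > 0, K > 0, lambda > 0)
  structure(list(n_iterations = n_iterations,
                 filter_min_score_per_res = filter_min_score_per_res,
                 search_evalue_cutoff = search_evalue_cutoff,
                 K = K, lambda = lambda),
            class = "boost_params")
}

# local DP of a profile against one sequence; counted as an alignment
profile_path <- function(pssm, t_res, matrix = blosum62()) {
  tc <- seq_codes(t_res, matrix)
  tl <- match(matrix$alphabet[tc], rownames(pssm$scores))
  qc <- seq_codes(pssm$consensus, matrix)
  S <- t(pssm$scores)[, tl, drop = FALSE]
  the$n_alignments <- the$n_alignments + 1L
  res <- sw_dp(S, qc, tc, matrix$gap_open, matrix$gap_extend)
  res$q_len <- pssm$n_cols
  res$t_len <- length(tc)
  res
}

#' Iterative profile search through a sequence database
#'
#' Local profile-sequence alignment of the PSSM against every database
#' sequence; hits with Karlin-Altschul E-value `K * n_cols * N_db *
#' exp(-lambda * score)` below the cutoff are collected.  Across iterations
#' the hits are merged into a center-star MSA around the profile consensus,
#' the profile is rebuilt and the search repeated, up to
#' `params$n_iterations` times or until no new hit appears; the hit set
#' grows monotonically.
#'
#' @param pssm A [build_pssm()] profile.
#' @param db Protein tibble to search.
#' @param params A [boost_params()].
#' @param matrix Substitution matrix.
#' @return A tibble of alignment results (one row per hit) with an `evalue`
#'   column, sorted by increasing E-value.
#' @export
profile_search <- function(pssm, db, params = boost_params(),
                           matrix = blosum62()) {
  if (!nrow(db)) abort("empty database")
  n_db <- sum(nchar(db$residues))
  hits <- NULL
  for (it in seq_len(params$n_iterations)) {
    found <- dplyr::bind_rows(lapply(seq_len(nrow(db)), function(i) {
      p <- profile_path(pssm, db$residues[i], matrix)
      row <- alignment_row(p, q_id = "profile", t_id = db$accession[i])
      row$evalue <- params$K * pssm$n_cols * n_db * exp(-params$lambda * p$score)
      row
    }))
    found <- found[found$evalue < params$search_evalue_cutoff, ]
    new <- found[!found$t_id %in% hits$t_id, ]
    hits <- dplyr::bind_rows(hits, new)
    if (!nrow(new) || it == params$n_iterations) break
    mem <- protein_tbl(
      accession = c("profile_consensus", hits$t_id),
      residues = c(pssm$consensus,
                   db$residues[match(hits$t_id, db$accession)]))
    pssm <- build_pssm(build_msa(mem, "profile_consensus", matrix), matrix)
  }
  hits[order(hits$evalue, hits$t_id), ]
}

#' Filter an MSA by score per aligned residue to the consensus
#'
#' A record is kept iff the mean substitution score of its aligned
#' match-state residues against the consensus reaches
#' `min_score_per_res`; lowercase insertions are unscored and deletion
#' columns are skipped.  The first record (representative or consensus
#' master) is always kept.  Higher thresholds give strictly nested, less
#' diverse alignments: the published tiers 0.0 / 0.5 / 1.1.
#'
#' @param m An [msa].
#' @param consensus A `consensus_record` or plain consensus string matching
#'   the MSA's match columns.
#' @param matrix Substitution matrix.
#' @param min_score_per_res Threshold.
#' @return The filtered [msa].
#' @export
diversity_filter <- function(m, consensus, matrix = blosum62(),
                             min_score_per_res = 0.0) {
  cons <- strsplit(consensus_seq(consensus), "")[[1]]
  if (length(cons) != m$n_match_columns)
    abort("consensus length must equal the MSA's match-column count")
  M <- msa_match_matrix(m)
  spr <- vapply(seq_along(m$accession), function(i) {
    obs <- M[i, ] != "-"
    if (!any(obs)) return(-Inf)
    mean(matrix$scores[cbind(M[i, obs], cons[obs])])
  }, numeric(1))
  keep <- spr >= min_score_per_res
  keep[1] <- TRUE
  msa(m$accession[keep], m$aligned[keep])
}

#' Diversify a cluster MSA by profile-search enrichment
#'
#' The boost workflow for one cluster: build a profile from the cluster MSA,
#' search a consensus-sequence database iteratively ([profile_search()]),
#' merge the hits into the alignment, and apply the
#' [diversity_filter()] against the cluster consensus at the requested
#' threshold.
#'
#' @param m The cluster [msa].
#' @param db Protein tibble of search targets (typically all cluster
#'   consensus sequences).
#' @param params A [boost_params()].
#' @param matrix Substitution matrix.
#' @return The enriched, filtered [msa].
#' @export
boost_msa <- function(m, db, params = boost_params(), matrix = blosum62()) {
  cons <- compute_consensus(m, matrix)
  hits <- profile_search(build_pssm(m, matrix), db, params, matrix)
  new_ids <- setdiff(hits$t_id, m$accession)
  if (length(new_ids)) {
    mem <- protein_tbl(
      accession = c(m$accession, new_ids),
      residues = c(toupper(gsub("-", "", m$aligned)),
                   db$residues[match(new_ids, db$accession)]))
    m <- build_msa(mem, m$accession[1], matrix)
  }
  diversity_filter(m, cons, matrix, params$filter_min_score_per_res)
}
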