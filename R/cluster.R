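#' Clustering parameters
#'
#' Bundles the thresholds of one clustering level.  Defaults follow the
#' published criteria: level 90 uses 90% identity with 90% coverage of the
#' shorter sequence; levels 50 and 30 use 50%/30% identity with 80%
#' bidirectional coverage.  The fragment rule (absorb near-identical
#' fragments covered over >= 95% of their own length at >= 90% identity) is
#' shared by all levels.
#'
#' @param level 90, 50 or 30.
#' @param min_seq_id Minimum identity to the representative.
#' @param min_cov Minimum alignment coverage.
#' @param cov_mode `"shorter"` (coverage of the shorter of the two sequences)
#'   or `"both"` (bidirectional).
#' @param fragment_min_id,fragment_min_cov Fragment-absorption thresholds
#'   (identity, member-side coverage).
#' @param release Release tag (`yymm`) used in generated cluster IDs.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(level = 90, min_seq_id = NULL, min_cov = NULL,
                           cov_mode = NULL, fragment_min_id = 0.9,
                           fragment_min_cov = 0.95, release = "0000") {
  level <- as.integer(level)
  defaults <- list(
    `90` = list(id = 0.9, cov = 0.9, mode = "shorter"),
    `50` = list(id = 0.5, cov = 0.8, mode = "both"),
    `30` = list(id = 0.3, cov = 0.8, mode = "both")
  )[[as.character(level)]]
  if (is.null(defaults) && (is.null(min_seq_id) || is.null(min_cov)))
    abort("unknown level: supply min_seq_id and min_cov explicitly")
  p <- list(
    level = level,
    min_seq_id = min_seq_id %||% defaults$id,
    min_cov = min_cov %||% defaults$cov,
    cov_mode = cov_mode %||% (defaults$mode %||% "both"),
    fragment_min_id = fragment_min_id,
    fragment_min_cov = fragment_min_cov,
    release = release
  )
  stopifnot(p$min_seq_id > 0, p$min_seq_id <= 1, p$min_cov > 0, p$min_cov <= 1,
            p$cov_mode %in% c("shorter", "both"))
  structure(p, class = "cluster_params")
}

# coverage criterion for an alignment row under a coverage mode
cov_ok <- function(al, min_cov, cov_mode) {
  if (cov_mode == "shorter") {
    cov <- ifelse(al$q_len <= al$t_len, al$q_cov, al$t_cov)
    cov >= min_cov
  } else {
    al$q_cov >= min_cov & al$t_cov >= min_cov
  }
}

eligible <- function(al, params) {
  al$n_aligned_cols > 0 & al$identity >= params$min_seq_id &
    cov_ok(al, params$min_cov, params$cov_mode)
}

# deterministic processing order used throughout: longest first, then
# lexicographically smallest accession
canonical_order <- function(seqs) {
  order(-nchar(seqs$residues), seqs$accession)
}

# pick the best candidate by (criterion desc, rep length desc, rep accession)
best_candidate <- function(crit, rep_len, rep_acc) {
  order(-crit, -rep_len, rep_acc)[1]
}

#' Redundancy clustering by reduced-alphabet hashing
#'
#' The fast first pass: sequences are reduced to a five-letter alphabet and
#' hashed ([hash64()]); only sequences of identical length with identical
#' hash fall into a common bucket, and a bucket member joins a cluster only
#' after verification that its exact column-wise identity to the cluster
#' representative (no alignment needed at equal length) reaches
#' `min_seq_id`.  Hash collisions therefore cannot cause wrong merges.
#'
#' @param seqs A protein tibble.
#' @param min_seq_id Verification identity threshold (default 0.9).
#' @param level,release Used for generated cluster IDs.
#' @return A `miniclust_clustering`.
#' @export
hash_cluster <- function(seqs, min_seq_id = 0.9, level = 90, release = "0000") {
  ord <- canonical_order(seqs)
  acc <- seqs$accession[ord]
  res <- seqs$residues[ord]
  key <- paste0(nchar(res), ":", hash64(reduce_alphabet(res)))
  reps <- character()
  members <- list()
  bucket_reps <- split(integer(), character())  # key -> indices into reps
  codes <- lapply(res, utf8ToInt)
  for (i in seq_along(acc)) {
    cand <- bucket_reps[[key[i]]]
    placed <- FALSE
    if (length(cand)) {
      ident <- vapply(cand, function(k) {
        mean(codes[[i]] == codes[[match(reps[k], acc)]])
      }, numeric(1))
      ok <- which(ident >= min_seq_id)
      if (length(ok)) {
        k <- cand[ok[which.max(ident[ok])]]
        members[[k]] <- c(members[[k]], acc[i])
        placed <- TRUE
      }
    }
    if (!placed) {
      reps <- c(reps, acc[i])
      members[[length(reps)]] <- acc[i]
      bucket_reps[[key[i]]] <- c(bucket_reps[[key[i]]], length(reps))
    }
  }
  clustering_from_list(members, reps, level, release)
}

#' Absorb sequence fragments into their full-length clusters
#'
#' A cluster (typically a short singleton) is dissolved into another cluster
#' when its representative aligns to that cluster's representative with
#' identity >= `fragment_min_id` and is covered over at least
#' `fragment_min_cov` of its own length.  Candidates are processed shortest
#' first and may only be absorbed by clusters with an equally long or longer
#' representative; among eligible targets the best-scoring alignment wins
#' (ties: longer representative, then accession).
#'
#' @param clustering A `miniclust_clustering`.
#' @param seqs Protein tibble covering all representatives.
#' @param params A [cluster_params()].
#' @param m Substitution matrix.
#' @return A `miniclust_clustering`.
#' @export
merge_fragments <- function(clustering, seqs, params = cluster_params(),
                            m = blosum62()) {
  tb <- as_tibble(clustering)
  reps <- unique(tb$representative)
  members <- lapply(reps, function(r) tb$member[tb$representative == r])
  names(members) <- reps
  res_of <- setNames(seqs$residues, seqs$accession)
  len_of <- nchar(res_of)
  alive <- setNames(rep(TRUE, length(reps)), reps)
  for (f in reps[order(len_of[reps], reps)]) {
    if (!alive[f]) next
    targets <- reps[alive & reps != f & len_of[reps] >= len_of[f]]
    if (!length(targets)) next
    als <- dplyr::bind_rows(lapply(targets, function(r) {
      align_pair(res_of[[f]], res_of[[r]], m, q_id = f, t_id = r)
    }))
    ok <- als$n_aligned_cols > 0 & als$identity >= params$fragment_min_id &
      als$q_cov >= params$fragment_min_cov
    if (!any(ok)) next
    als <- als[ok, ]
    tgt <- als$t_id[best_candidate(als$score, len_of[als$t_id], als$t_id)]
    members[[tgt]] <- c(members[[tgt]], members[[f]])
    alive[f] <- FALSE
  }
  clustering_from_list(members[alive], reps[alive],
                       params$level, params$release)
}

#' Greedy incremental clustering
#'
#' The CD-HIT-style strategy: sequences are processed longest first (ties by
#' accession); each either joins the best-scoring existing representative
#' that satisfies the identity and coverage thresholds, or founds a new
#' cluster with itself as representative.  Representatives are therefore the
#' longest members of their clusters.
#'
#' @inheritParams merge_fragments
#' @param seqs A protein tibble.
#' @return A `miniclust_clustering`.
#' @export
greedy_incremental_cluster <- function(seqs, params = cluster_params(),
                                       m = blosum62()) {
  ord <- canonical_order(seqs)
  acc <- seqs$accession[ord]
  res <- seqs$residues[ord]
  len <- nchar(res)
  reps_i <- integer()
  members <- list()
  for (i in seq_along(acc)) {
    joined <- FALSE
    if (length(reps_i)) {
      als <- dplyr::bind_rows(lapply(reps_i, function(k) {
        align_pair(res[i], res[k], m, q_id = acc[i], t_id = acc[k])
      }))
      ok <- which(eligible(als, params))
      if (length(ok)) {
        k <- ok[best_candidate(als$score[ok], len[reps_i[ok]], acc[reps_i[ok]])]
        members[[k]] <- c(members[[k]], acc[i])
        joined <- TRUE
      }
    }
    if (!joined) {
      reps_i <- c(reps_i, i)
      members[[length(reps_i)]] <- acc[i]
    }
  }
  clustering_from_list(members, acc[reps_i], params$level, params$release)
}

#' Greedy set cover over an explicit acceptance graph
#'
#' Repeatedly selects the uncovered vertex whose closed neighbourhood covers
#' the most still-uncovered vertices (ties: longest sequence, then smallest
#' accession) as the representative of a new cluster containing itself and
#' its uncovered neighbours, until every vertex is covered.
#'
#' @param vertices Tibble with columns `id` and `length`.
#' @param edges Tibble with columns `from`, `to` (undirected; self edges
#'   ignored).
#' @param level,release Used for generated cluster IDs.
#' @return A `miniclust_clustering`.
#' @export
greedy_set_cover <- function(vertices, edges, level = 30, release = "0000") {
  ids <- vertices$id
  len <- setNames(vertices$length, ids)
  nbr <- setNames(rep(list(character()), length(ids)), ids)
  if (nrow(edges)) {
    e <- edges[edges$from != edges$to, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      nbr[[e$from[k]]] <- union(nbr[[e$from[k]]], e$to[k])
      nbr[[e$to[k]]] <- union(nbr[[e$to[k]]], e$from[k])
    }
  }
  uncovered <- ids
  reps <- character()
  members <- list()
  while (length(uncovered)) {
    gain <- vapply(uncovered,
                   function(v) 1L + sum(nbr[[v]] %in% uncovered), integer(1))
    v <- uncovered[best_candidate(gain, len[uncovered], uncovered)]
    cl <- c(v, intersect(nbr[[v]], uncovered))
    reps <- c(reps, v)
    members[[length(reps)]] <- cl
    uncovered <- setdiff(uncovered, cl)
  }
  clustering_from_list(members, reps, level, release)
}

#' Greedy set-cover clustering with reassignment
#'
#' Builds the undirected acceptance graph over the input sequences — an edge
#' joins two sequences whose alignment reaches the identity threshold with
#' bidirectional coverage — runs [greedy_set_cover()] on it, then applies
#' one [reassign_members()] pass so every member sits with the
#' representative most similar to it.
#'
#' @inheritParams greedy_incremental_cluster
#' @return A `miniclust_clustering`.
#' @export
set_cover_cluster <- function(seqs, params = cluster_params(30),
                              m = blosum62()) {
  n <- nrow(seqs)
  from <- character(); to <- character()
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        al <- align_pair(seqs$residues[i], seqs$residues[j], m,
                         q_id = seqs$accession[i], t_id = seqs$accession[j])
        if (eligible(al, params)) {
          from <- c(from, seqs$accession[i])
          to <- c(to, seqs$accession[j])
        }
      }
    }
  }
  cl <- greedy_set_cover(
    tibble(id = seqs$accession, length = nchar(seqs$residues)),
    tibble(from = from, to = to),
    level = params$level, release = params$release
  )
  reassign_members(cl, seqs, params, m)
}

#' Reassign members to their most similar representative
#'
#' One pass over all non-representative members: each moves to the
#' representative (over all clusters) with the highest score per aligned
#' residue among those still satisfying the identity and coverage
#' thresholds.  Representatives never move.
#'
#' @inheritParams merge_fragments
#' @return A `miniclust_clustering`.
#' @export
reassign_members <- function(clustering, seqs, params = cluster_params(30),
                             m = blosum62()) {
  tb <- as_tibble(clustering)
  reps <- unique(tb$representative)
  res_of <- setNames(seqs$residues, seqs$accession)
  len_of <- nchar(res_of)
  members <- setNames(lapply(reps, function(r) r), reps)
  for (mem in tb$member[!tb$member %in% reps]) {
    cur <- tb$representative[tb$member == mem]
    als <- dplyr::bind_rows(lapply(reps, function(r) {
      align_pair(res_of[[mem]], res_of[[r]], m, q_id = mem, t_id = r)
    }))
    ok <- which(eligible(als, params))
    tgt <- if (length(ok)) {
      reps[ok[best_candidate(als$score_per_res[ok], len_of[reps[ok]], reps[ok])]]
    } else cur
    members[[tgt]] <- c(members[[tgt]], mem)
  }
  clustering_from_list(members, reps, params$level, params$release)
}

# replace each member of `coarse` (a representative of `fine`) by the full
# member list of its fine cluster
expand_clustering <- function(coarse, fine, level, release) {
  ctb <- as_tibble(coarse)
  ftb <- as_tibble(fine)
  fine_members <- split(ftb$member, ftb$representative)
  reps <- unique(ctb$representative)
  members <- lapply(reps, function(r) {
    unlist(fine_members[ctb$member[ctb$representative == r]],
           use.names = FALSE)
  })
  clustering_from_list(members, reps, level, release)
}

#' Cascaded three-level clustering
#'
#' The full clustering workflow: (1) redundancy filtering by
#' reduced-alphabet hashing plus fragment absorption; (2) greedy incremental
#' clustering of the remaining representatives at 90% identity / 90%
#' coverage of the shorter sequence, again followed by the fragment rule,
#' giving the 90% level; (3) greedy set-cover clustering with reassignment
#' of the 90%-level representatives at 50% and, independently, at 30%
#' identity with 80% bidirectional coverage.  Coarse memberships are
#' expanded through the finer levels, so every input sequence appears in all
#' three partitions and every coarse cluster is a union of whole 90%-level
#' clusters.
#'
#' @param seqs A protein tibble.
#' @param release Release tag (`yymm`) for cluster IDs.
#' @param m Substitution matrix.
#' @param levels Coarse levels to build beyond 90 (subset of c(50, 30)).
#' @return Named list of `miniclust_clustering` objects: `uc90`, `uc50`,
#'   `uc30`.
#' @export
cascade <- function(seqs, release = "0000", m = blosum62(),
                    levels = c(50, 30)) {
  p90 <- cluster_params(90, release = release)
  s1 <- hash_cluster(seqs, p90$min_seq_id, level = 90, release = release)
  s1 <- merge_fragments(s1, seqs, p90, m)
  reps1 <- seqs[match(unique(s1$representative), seqs$accession), ]
  s2 <- greedy_incremental_cluster(reps1, p90, m)
  s2 <- merge_fragments(s2, reps1, p90, m)
  uc90 <- expand_clustering(s2, s1, 90, release)
  reps90 <- seqs[match(unique(uc90$representative), seqs$accession), ]
  out <- list(uc90 = uc90)
  for (lv in levels) {
    plv <- cluster_params(lv, release = release)
    slv <- set_cover_cluster(reps90, plv, m)
    out[[paste0("uc", lv)]] <- expand_clustering(slv, uc90, lv, release)
  }
  out
}

#' Incrementally update a clustering
#'
#' Updates an existing partition to a new sequence set without reclustering
#' from scratch, keeping cluster identifiers stable: deprecated members are
#' dropped (a cluster whose representative disappeared promotes its longest
#' remaining member and keeps its identifier); genuinely new sequences are
#' compared against surviving representatives only — linear in new sequences
#' times representatives, never all-vs-all — and join the best eligible one;
#' the remainder is clustered among itself by greedy set cover and receives
#' fresh identifiers.
#'
#' @param old A `miniclust_clustering` over `old_seqs`.
#' @param old_seqs,new_seqs Protein tibbles.  Accessions are immutable: an
#'   accession present in both with different residues is an error.
#' @param params A [cluster_params()]; `params$release` tags new clusters.
#' @param m Substitution matrix.
#' @return A `miniclust_clustering` over `new_seqs`.
#' @export
update_clustering <- function(old, old_seqs, new_seqs,
                              params = cluster_params(90), m = blosum62()) {
  otb <- as_tibble(old)
  common <- intersect(old_seqs$accession, new_seqs$accession)
  changed <- common[old_seqs$residues[match(common, old_seqs$accession)] !=
                      new_seqs$residues[match(common, new_seqs$accession)]]
  if (length(changed))
    abort(sprintf("accessions are immutable, but residues changed for: %s",
                  paste(head(changed, 5), collapse = ", ")))
  len_of <- setNames(nchar(new_seqs$residues), new_seqs$accession)
  res_of <- setNames(new_seqs$residues, new_seqs$accession)

  # drop deprecated members; promote representatives where needed
  keep <- otb[otb$member %in% new_seqs$accession, ]
  ids <- unique(otb$cluster_id)
  reps <- character(); members <- list(); out_ids <- character()
  for (cid in ids) {
    mem <- keep$member[keep$cluster_id == cid]
    if (!length(mem)) next
    r <- otb$representative[otb$cluster_id == cid][1]
    if (!r %in% mem)
      r <- mem[order(-len_of[mem], mem)][1]
    reps <- c(reps, r)
    members[[length(reps)]] <- union(r, mem)
    out_ids <- c(out_ids, cid)
  }

  # new sequences: compare to surviving representatives only
  added <- setdiff(new_seqs$accession, old_seqs$accession)
  leftovers <- character()
  for (a in added) {
    tgt <- NULL
    if (length(reps)) {
      als <- dplyr::bind_rows(lapply(reps, function(r) {
        align_pair(res_of[[a]], res_of[[r]], m, q_id = a, t_id = r)
      }))
      ok <- which(eligible(als, params))
      if (length(ok))
        tgt <- ok[best_candidate(als$score_per_res[ok], len_of[reps[ok]],
                                 reps[ok])]
    }
    if (is.null(tgt)) leftovers <- c(leftovers, a)
    else members[[tgt]] <- c(members[[tgt]], a)
  }

  out <- clustering_from_list(members, reps, params$level, params$release,
                              cluster_id = out_ids)
  if (length(leftovers)) {
    fresh <- set_cover_cluster(new_seqs[new_seqs$accession %in% leftovers, ],
                               params, m)
    n0 <- max(c(0L, suppressWarnings(
      as.integer(sub("^.*-", "", ids)))), na.rm = TRUE)
    ftb <- as_tibble(fresh)
    num <- match(ftb$cluster_id, unique(ftb$cluster_id))
    ftb$cluster_id <- sprintf("uc%d-%s-%d", params$level, params$release,
                              n0 + num)
    out <- validate_clustering(dplyr::bind_rows(as_tibble(out), ftb))
  }
  out
}
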