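#' Clustering tables
#'
#' A clustering is a tidy tibble with one row per cluster member and columns
#' `cluster_id`, `representative`, `member`.  It always contains the
#' representative's self-row, member sets of distinct clusters are disjoint,
#' and cluster identifiers follow the `uc<level>-<yymm>-<number>` convention.
#'
#' @param representative,member Parallel character vectors (one row per
#'   membership pair; must include each representative's self-pair).
#' @param cluster_id Optional explicit identifiers; regenerated from `level`
#'   and `release` in order of first appearance of each representative when
#'   omitted.
#' @param level Clustering level (90, 50 or 30), used in generated IDs.
#' @param release Release tag in `yymm` form, used in generated IDs.
#' @return A tibble of class `miniclust_clustering`.
#' @export
clustering_tbl <- function(representative, member, cluster_id = NULL,
                           level = 90, release = "0000") {
  tbl <- tibble(representative = as.character(representative),
                member = as.character(member))
  if (is.null(cluster_id)) {
    reps <- unique(tbl$representative)
    ids <- setNames(cluster_ids(length(reps), level, release), reps)
    tbl$cluster_id <- unname(ids[tbl$representative])
  } else {
    tbl$cluster_id <- as.character(cluster_id)
  }
  validate_clustering(tbl[, c("cluster_id", "representative", "member")])
}

cluster_ids <- function(n, level, release) {
  if (!grepl("^[0-9]{4}$", release))
    abort("release tag must match yymm (four digits)")
  sprintf("uc%d-%s-%d", as.integer(level), release, seq_len(n))
}

validate_clustering <- function(tbl) {
  if (anyDuplicated(tbl$member))
    abort("clusters are not disjoint: a member appears twice")
  by_id <- split(tbl, tbl$cluster_id)
  for (cl in by_id) {
    if (length(unique(cl$representative)) != 1L)
      abort(sprintf("cluster %s has multiple representatives", cl$cluster_id[1]))
    if (!cl$representative[1] %in% cl$member)
      abort(sprintf("representative %s missing its self-row", cl$representative[1]))
  }
  class(tbl) <- unique(c("miniclust_clustering", class(tbl)))
  tbl
}

# internal: clustering from a list of member-vectors, reps = first elements
clustering_from_list <- function(members_list, reps, level = 90,
                                 release = "0000", cluster_id = NULL) {
  n <- lengths(members_list)
  ids <- cluster_id %||% cluster_ids(length(reps), level, release)
  clustering_tbl(
    representative = rep(reps, n),
    member = unlist(members_list, use.names = FALSE),
    cluster_id = rep(ids, n),
    level = level, release = release
  )
}

#' @export
print.miniclust_clustering <- function(x, ...) {
  cat(sprintf("<clustering> %d clusters, %d members\n",
              length(unique(x$cluster_id)), nrow(x)))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize clusterings
#'
#' `tidy()` returns one row per cluster with its size; `glance()` returns
#' the database-level statistics usually reported for clustered protein
#' databases: cluster count, singleton count, and mean cluster size over all
#' and over non-singleton clusters.
#'
#' @param x A `miniclust_clustering`.
#' @param ... Unused.
#' @export
tidy.miniclust_clustering <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(as_tibble(x), .data$cluster_id,
                                   .data$representative),
                   size = dplyr::n(), .groups = "drop")
}

#' @rdname tidy.miniclust_clustering
#' @export
glance.miniclust_clustering <- function(x, ...) {
  sizes <- tidy(x)$size
  tibble(n_clusters = length(sizes),
         n_members = sum(sizes),
         n_singletons = sum(sizes == 1L),
         mean_size = mean(sizes),
         mean_size_nonsingleton = if (any(sizes > 1)) mean(sizes[sizes > 1]) else NA_real_)
}

#' Write and read the two-column cluster membership TSV
#'
#' One line per (representative, member) pair, self-pairs included: the
#' standard cluster mapping exchange format.  Cluster identifiers are not
#' part of the two-column format; `write_cluster_tsv(id_map = TRUE)` writes a
#' `<path>.ids` sidecar mapping representatives to identifiers, which
#' `read_cluster_tsv()` picks up automatically; otherwise identifiers are
#' regenerated deterministically from representative order of appearance.
#'
#' @param clustering A `miniclust_clustering`.
#' @param path Output path.
#' @param id_map Write the identifier sidecar?
#' @param level,release Used to regenerate identifiers on read when no
#'   sidecar is present.
#' @export
write_cluster_tsv <- function(clustering, path, id_map = FALSE) {
  validate_clustering(as_tibble(clustering))
  readr::write_tsv(as_tibble(clustering)[, c("representative", "member")],
                   path, col_names = FALSE)
  if (id_map) {
    ids <- unique(as_tibble(clustering)[, c("representative", "cluster_id")])
    readr::write_tsv(ids, paste0(path, ".ids"), col_names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cluster_tsv
#' @export
read_cluster_tsv <- function(path, level = 90, release = "0000") {
  tbl <- readr::read_tsv(path, col_names = c("representative", "member"),
                         col_types = "cc", progress = FALSE)
  if (!nrow(tbl)) abort(sprintf("'%s' is empty", path))
  raw <- readLines(path)
  if (any(lengths(strsplit(raw[nzchar(raw)], "\t", fixed = TRUE)) != 2L))
    abort("cluster TSV lines must have exactly two tab-separated fields")
  sidecar <- paste0(path, ".ids")
  if (file.exists(sidecar)) {
    ids <- readr::read_tsv(sidecar, col_names = c("representative", "cluster_id"),
                           col_types = "cc", progress = FALSE)
    id_of <- setNames(ids$cluster_id, ids$representative)
    clustering_tbl(tbl$representative, tbl$member,
                   cluster_id = unname(id_of[tbl$representative]))
  } else {
    clustering_tbl(tbl$representative, tbl$member, level = level,
                   release = release)
  }
}
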