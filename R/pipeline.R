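#' Pipeline configuration
#'
#' Bundles every tunable of a database build: the release tag stamped into
#' cluster identifiers, the clustering levels to produce, the boost filter
#' tiers, the E-value and overlap constants of annotation transfer, and the
#' seed controlling all sampling.
#'
#' @param release Release tag (`yymm`).
#' @param levels Clustering levels (subset of c(90, 50, 30); 90 is always
#'   built first as the cascade base).
#' @param boost_filters Score-per-residue thresholds of the boost tiers to
#'   emit (named by diversity level), or `NULL` to skip boosting.
#' @param max_len Long-sequence split threshold.
#' @param seed Integer seed.
#' @param transfer A [transfer_params()].
#' @param boost A [boost_params()].
#' @param log_path Optional path receiving a line per pipeline decision.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(release = "0001", levels = c(90, 50, 30),
                            boost_filters = c(boost10 = 0.0, boost20 = 0.5,
                                              boost30 = 1.1),
                            max_len = 14000, seed = 1,
                            transfer = transfer_params(),
                            boost = boost_params(), log_path = NULL) {
  if (!grepl("^[0-9]{4}$", release))
    abort("release tag must match yymm (four digits)")
  stopifnot(90 %in% levels)
  structure(list(release = release, levels = levels,
                 boost_filters = boost_filters, max_len = max_len,
                 seed = seed, transfer = transfer, boost = boost,
                 log_path = log_path),
            class = "pipeline_config")
}

#' Build a clustered database release from a FASTA file
#'
#' End-to-end workflow: long-sequence splitting, cascaded clustering at the
#' configured levels, per-cluster MSAs at the deepest level, consensus
#' sequences with annotation summary headers, optional boost MSAs, optional
#' annotation transfer, and a machine-readable manifest.  Output files are
#' staged and atomically renamed into place, so a failed run leaves no
#' partial release.  Idempotent under a fixed seed.
#'
#' @param fasta Input FASTA path, or a protein tibble.
#' @param out_dir Output directory (must not exist).
#' @param config A [pipeline_config()].
#' @param annotations Optional annotation tibble on the deepest level's
#'   consensus coordinates, transferred to members.
#' @param m Substitution matrix.
#' @return `out_dir`, invisibly; see the written `manifest.json` for the
#'   file inventory.
#' @export
run_build <- function(fasta, out_dir, config = pipeline_config(),
                      annotations = NULL, m = blosum62()) {
  seqs <- if (is.data.frame(fasta)) fasta else parse_fasta(fasta)
  if (!nrow(seqs)) abort("build: input contains no sequences")
  if (dir.exists(out_dir)) abort(sprintf("build: '%s' already exists", out_dir))
  seqs <- split_long_sequences(seqs, config$max_len)
  log_line(config$log_path, "build: %d sequences after splitting", nrow(seqs))

  stage <- paste0(out_dir, ".staging")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))

  clusterings <- cascade(seqs, release = config$release, m = m,
                         levels = setdiff(config$levels, 90))
  write_fasta(seqs, file.path(stage, "input_sequences.fasta"))
  deepest <- paste0("uc", min(config$levels))
  manifest <- list(release = config$release, seed = config$seed,
                   n_sequences = nrow(seqs), levels = as.list(config$levels))
  for (nm in names(clusterings)) {
    cl <- clusterings[[nm]]
    write_cluster_tsv(cl, file.path(stage, paste0(nm, "_cluster.tsv")),
                      id_map = TRUE)
    reps <- unique(cl$representative)
    write_fasta(seqs[match(reps, seqs$accession), ],
                file.path(stage, paste0(nm, "_seed.fasta")))
    manifest[[paste0("n_clusters_", nm)]] <- length(reps)
  }

  # MSAs + consensus at the deepest level
  cl <- clusterings[[deepest]]
  tb <- as_tibble(cl)
  dir.create(file.path(stage, "msa"))
  cons_acc <- character(); cons_res <- character(); cons_hdr <- character()
  msas <- list()
  for (cid in unique(tb$cluster_id)) {
    rows <- tb[tb$cluster_id == cid, ]
    members <- seqs[match(rows$member, seqs$accession), ]
    mm <- build_msa(members, rows$representative[1], m)
    write_a3m(mm, file.path(stage, "msa", paste0(cid, ".a3m")))
    cons <- compute_consensus(mm, m)
    cons_acc <- c(cons_acc, cid)
    cons_res <- c(cons_res, cons$sequence)
    cons_hdr <- c(cons_hdr, summarize_headers(members, cid,
                                              rows$representative[1]))
    msas[[cid]] <- mm
  }
  cons_tbl <- protein_tbl(cons_acc, cons_res,
                          description = sub("^[^|]*\\|", "", cons_hdr))
  write_fasta(cons_tbl, file.path(stage, paste0(deepest, "_consensus.fasta")))

  if (!is.null(config$boost_filters)) {
    for (tier in names(config$boost_filters)) {
      dir.create(file.path(stage, tier))
      bp <- config$boost
      bp$filter_min_score_per_res <- config$boost_filters[[tier]]
      for (cid in names(msas)) {
        bm <- boost_msa(msas[[cid]], cons_tbl, bp, m)
        write_a3m(bm, file.path(stage, tier, paste0(cid, ".a3m")))
      }
    }
  }

  if (!is.null(annotations) && nrow(annotations)) {
    transferred <- list()
    for (cid in intersect(unique(annotations$query_id), names(msas))) {
      ann <- annotations[annotations$query_id == cid, ]
      acc <- accept_annotations(ann, config$transfer)
      rows <- tb[tb$cluster_id == cid, ]
      members <- seqs[match(rows$member, seqs$accession), ]
      cons <- cons_tbl$residues[match(cid, cons_tbl$accession)]
      transferred[[cid]] <- transfer_annotations(acc, msas[[cid]], cons,
                                                 members, m, config$transfer)
    }
    out_ann <- dplyr::bind_rows(transferred)
    write_annotation_tsv(out_ann, file.path(stage, "annotations.tsv"))
    manifest$n_annotations_transferred <- nrow(out_ann)
  }

  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!file.rename(stage, out_dir))
    abort("build: could not move staging directory into place")
  ok <- TRUE
  log_line(config$log_path, "build: release %s written to %s",
           config$release, out_dir)
  invisible(out_dir)
}

#' Incrementally update a built release
#'
#' Reads a previous [run_build()]/[run_update()] output directory, applies
#' [update_clustering()] at every level against the new sequence set, and
#' rebuilds MSAs and consensus sequences only for clusters whose membership
#' changed; unchanged clusters keep their identifiers, representatives and
#' alignment files.
#'
#' @param old_dir Previous output directory.
#' @param fasta New sequence set (FASTA path or protein tibble).
#' @param out_dir Output directory (must not exist).
#' @param config A [pipeline_config()]; its release tag must be strictly
#'   newer than the old release.
#' @param m Substitution matrix.
#' @return `out_dir`, invisibly.
#' @export
run_update <- function(old_dir, fasta, out_dir, config = pipeline_config(),
                       m = blosum62()) {
  manifest <- jsonlite::read_json(file.path(old_dir, "manifest.json"))
  if (as.integer(config$release) <= as.integer(manifest$release))
    abort(sprintf("release tag %s is not newer than %s", config$release,
                  manifest$release))
  if (dir.exists(out_dir)) abort(sprintf("update: '%s' already exists", out_dir))
  old_seqs <- parse_fasta(file.path(old_dir, "input_sequences.fasta"))
  new_seqs <- if (is.data.frame(fasta)) fasta else parse_fasta(fasta)
  if (!nrow(new_seqs)) abort("update: input contains no sequences")
  new_seqs <- split_long_sequences(new_seqs, config$max_len)

  stage <- paste0(out_dir, ".staging")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))
  write_fasta(new_seqs, file.path(stage, "input_sequences.fasta"))
  out_manifest <- list(release = config$release, seed = config$seed,
                       n_sequences = nrow(new_seqs),
                       levels = manifest$levels, updated_from = manifest$release)

  levels <- sort(unlist(manifest$levels), decreasing = TRUE)
  deepest <- paste0("uc", min(levels))
  for (lv in levels) {
    nm <- paste0("uc", lv)
    old_cl <- read_cluster_tsv(file.path(old_dir, paste0(nm, "_cluster.tsv")))
    new_cl <- update_clustering(old_cl, old_seqs, new_seqs,
                                cluster_params(lv, release = config$release), m)
    write_cluster_tsv(new_cl, file.path(stage, paste0(nm, "_cluster.tsv")),
                      id_map = TRUE)
    reps <- unique(new_cl$representative)
    write_fasta(new_seqs[match(reps, new_seqs$accession), ],
                file.path(stage, paste0(nm, "_seed.fasta")))
    out_manifest[[paste0("n_clusters_", nm)]] <- length(reps)
    if (nm == deepest) {
      dir.create(file.path(stage, "msa"))
      otb <- as_tibble(old_cl); ntb <- as_tibble(new_cl)
      old_members <- split(otb$member, otb$cluster_id)
      cons_acc <- character(); cons_res <- character(); cons_hdr <- character()
      changed <- 0L
      for (cid in unique(ntb$cluster_id)) {
        rows <- ntb[ntb$cluster_id == cid, ]
        unchanged <- !is.null(old_members[[cid]]) &&
          setequal(old_members[[cid]], rows$member) &&
          file.exists(file.path(old_dir, "msa", paste0(cid, ".a3m")))
        if (unchanged) {
          file.copy(file.path(old_dir, "msa", paste0(cid, ".a3m")),
                    file.path(stage, "msa", paste0(cid, ".a3m")))
          mm <- parse_a3m(file.path(stage, "msa", paste0(cid, ".a3m")))
        } else {
          changed <- changed + 1L
          members <- new_seqs[match(rows$member, new_seqs$accession), ]
          mm <- build_msa(members, rows$representative[1], m)
          write_a3m(mm, file.path(stage, "msa", paste0(cid, ".a3m")))
        }
        members <- new_seqs[match(rows$member, new_seqs$accession), ]
        cons <- compute_consensus(mm, m)
        cons_acc <- c(cons_acc, cid)
        cons_res <- c(cons_res, cons$sequence)
        cons_hdr <- c(cons_hdr, summarize_headers(members, cid,
                                                  rows$representative[1]))
      }
      cons_tbl <- protein_tbl(cons_acc, cons_res,
                              description = sub("^[^|]*\\|", "", cons_hdr))
      write_fasta(cons_tbl, file.path(stage, paste0(deepest, "_consensus.fasta")))
      out_manifest$n_msas_recomputed <- changed
      log_line(config$log_path, "update: %d MSAs recomputed", changed)
    }
  }
  jsonlite::write_json(out_manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!file.rename(stage, out_dir))
    abort("update: could not move staging directory into place")
  ok <- TRUE
  invisible(out_dir)
}
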