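withr_tempfile <- function() tempfile(fileext = ".txt")

# coverage criterion of an alignment row under a parameter set
cov_of <- function(al, params) {
  if (params$cov_mode == "shorter") {
    if (al$q_len <= al$t_len) al$q_cov >= params$min_cov
    else al$t_cov >= params$min_cov
  } else {
    al$q_cov >= params$min_cov && al$t_cov >= params$min_cov
  }
}

# adjusted Rand index between a clustering and a planted partition
ari_vs_partition <- function(clustering, partition) {
  tb <- as.data.frame(clustering)
  labels <- tb$cluster_id[match(partition$accession, tb$member)]
  mclust::adjustedRandIndex(labels, partition$family)
}
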