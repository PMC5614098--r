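test_that("hash clustering merges only equal-length, verified-identical sequences", {
  s <- random_protein(1, 80)
  seqs <- protein_tbl(c("A1", "A2"), c(s, s))
  cl <- hash_cluster(seqs)
  expect_equal(length(unique(cl$cluster_id)), 1L)

  # same reduced-alphabet bucket, but only 85% exact identity: stays apart
  s1 <- strrep("I", 20)
  s2 <- paste0(strrep("I", 17), "LLL")
  expect_equal(reduce_alphabet(s1), reduce_alphabet(s2))
  cl <- hash_cluster(protein_tbl(c("B1", "B2"), c(s1, s2)), min_seq_id = 0.9)
  expect_equal(length(unique(cl$cluster_id)), 2L)

  # lengths 100 and 101 with identical prefix: never merged here
  s <- random_protein(1, 100)
  cl <- hash_cluster(protein_tbl(c("C1", "C2"), c(s, paste0(s, "A"))))
  expect_equal(length(unique(cl$cluster_id)), 2L)
})

test_that("fragment absorption follows the 90%-identity / 95%-self-coverage rule", {
  set.seed(31)
  full <- random_protein(1, 100)
  frag <- substr(full, 1, 50)
  seqs <- protein_tbl(c("FULL", "FRAG"), c(full, frag))
  cl0 <- hash_cluster(seqs)
  expect_equal(length(unique(cl0$cluster_id)), 2L)
  cl <- merge_fragments(cl0, seqs)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(unique(cl$representative), "FULL")

  # fragment aligning over only 90% of its own length is not absorbed
  base <- paste0(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                        100, replace = TRUE), collapse = "")
  frag2 <- paste0(substr(base, 1, 45), strrep("W", 5))
  seqs2 <- protein_tbl(c("FULL", "FRAG"), c(base, frag2))
  al <- align_pair(frag2, base)
  expect_lt(al$q_cov, 0.95)
  cl2 <- merge_fragments(hash_cluster(seqs2), seqs2)
  expect_equal(length(unique(cl2$cluster_id)), 2L)

  # nothing eligible: output identical to input
  seqs3 <- random_proteins_tbl(4, 60)
  cl3 <- hash_cluster(seqs3)
  expect_equal(partition_of(merge_fragments(cl3, seqs3)), partition_of(cl3))
})

test_that("greedy incremental clustering joins the best eligible representative", {
  set.seed(32)
  s <- random_protein(1, 100)
  seqs <- protein_tbl(c("A1", "A2", "B1"), c(s, s, random_protein(1, 100)))
  cl <- greedy_incremental_cluster(seqs, cluster_params(90))
  expect_equal(length(unique(cl$cluster_id)), 2L)

  single <- protein_tbl("X", random_protein(1, 50))
  cl1 <- greedy_incremental_cluster(single)
  expect_equal(as.data.frame(cl1)$member, "X")
  expect_equal(as.data.frame(cl1)$representative, "X")

  # partition is invariant under input shuffling
  fam <- generate_families(2, 4, 150, 0.95, fragment_prob = 0, seed = 5)
  p1 <- partition_of(greedy_incremental_cluster(fam$sequences))
  shuffled <- fam$sequences[sample(nrow(fam$sequences)), ]
  p2 <- partition_of(greedy_incremental_cluster(shuffled))
  expect_equal(p1, p2)

  # representatives are the longest members of their clusters
  fam2 <- generate_families(2, 5, 150, 0.95, fragment_prob = 0.5, seed = 6)
  cl2 <- as.data.frame(greedy_incremental_cluster(fam2$sequences))
  len <- setNames(nchar(fam2$sequences$residues), fam2$sequences$accession)
  expect_true(all(len[cl2$representative] >= len[cl2$member]))
})

test_that("set cover on explicit graphs matches the spec example and the oracle", {
  v <- tibble::tibble(id = as.character(1:5), length = c(100, 90, 80, 70, 60))
  e <- tibble::tibble(from = c("1", "1", "4"), to = c("2", "3", "5"))
  cl <- greedy_set_cover(v, e)
  expect_equal(partition_of(cl), list(c("1", "2", "3"), c("4", "5")))
  expect_equal(unique(as.data.frame(cl)$representative), c("1", "4"))

  # edgeless graph: all singletons
  cl0 <- greedy_set_cover(v, e[0, ])
  expect_equal(length(unique(cl0$cluster_id)), 5L)

  set.seed(33)
  for (k in 1:30) {
    g <- random_graph(sample(4:12, 1))
    got <- partition_of(greedy_set_cover(g$vertices, g$edges))
    want <- oracle_set_cover(g$vertices$id, g$len, g$edges)
    expect_equal(got, want)
  }
})

test_that("reassignment moves members to the highest score-per-residue representative", {
  set.seed(34)
  h <- hierarchical_fixture(3, 4, 120, seed = 9)
  params <- cluster_params(30)
  cl <- set_cover_cluster(h$sequences, params)
  tb <- as.data.frame(cl)
  reps <- unique(tb$representative)
  res <- setNames(h$sequences$residues, h$sequences$accession)
  # post-state: every member satisfies the thresholds to its own
  # representative and is at least as similar to it (score per residue) as
  # to any other eligible representative
  for (i in seq_len(nrow(tb))) {
    mem <- tb$member[i]
    if (mem %in% reps) next
    own_al <- align_pair(res[[mem]], res[[tb$representative[i]]])
    expect_true(own_al$identity >= params$min_seq_id &&
                  own_al$q_cov >= params$min_cov &&
                  own_al$t_cov >= params$min_cov)
    for (r in setdiff(reps, tb$representative[i])) {
      al <- align_pair(res[[mem]], res[[r]])
      elig <- al$identity >= params$min_seq_id &&
        al$q_cov >= params$min_cov && al$t_cov >= params$min_cov
      if (elig) expect_gte(own_al$score_per_res, al$score_per_res)
    }
  }
})

test_that("the cascade recovers planted families and nests its levels", {
  fam <- generate_families(3, 5, 200, 0.95, seed = 42)
  cls <- cascade(fam$sequences, release = "1603")
  for (nm in c("uc90", "uc50", "uc30")) {
    expect_equal(length(unique(cls[[nm]]$cluster_id)), 3L)
    expect_equal(ari_vs_partition(cls[[nm]], fam$partition), 1.0)
    expect_true(all(grepl(sprintf("^uc%s-1603-\\d+$", sub("uc", "", nm)),
                          cls[[nm]]$cluster_id)))
  }
  # single sequence: one singleton at every level
  single <- protein_tbl("X", random_protein(1, 80))
  cls1 <- cascade(single)
  expect_true(all(vapply(cls1, nrow, 1L) == 1L))

  # every coarse cluster is a union of whole uc90 clusters
  h <- hierarchical_fixture(seed = 2)
  cls2 <- cascade(h$sequences)
  uc90 <- split(cls2$uc90$member, cls2$uc90$cluster_id)
  for (coarse in list(cls2$uc50, cls2$uc30)) {
    blocks <- split(coarse$member, coarse$cluster_id)
    for (b in blocks) {
      covered <- vapply(uc90, function(f) all(f %in% b) || !any(f %in% b),
                        logical(1))
      expect_true(all(covered))
    }
  }
  # the 30% level merges the superfamilies the 90% level keeps apart
  expect_equal(length(unique(cls2$uc90$cluster_id)), 6L)
  expect_equal(length(unique(cls2$uc30$cluster_id)), 3L)
})

test_that("incremental update keeps identifiers stable and is linear in new x reps", {
  fam <- generate_families(3, 5, 200, 0.95, seed = 42)
  seqs <- fam$sequences
  old <- cascade(seqs, release = "1603")$uc90
  p90 <- cluster_params(90, release = "1605")

  # fixed point
  up <- update_clustering(old, seqs, seqs, p90)
  expect_identical(as.data.frame(up), as.data.frame(old))

  # duplicate of an existing representative joins its cluster, no new cluster
  rep1 <- unique(old$representative)[1]
  dup <- protein_tbl("NEW1", seqs$residues[seqs$accession == rep1])
  new_seqs <- dplyr::bind_rows(seqs, dup)
  reset_alignment_count()
  up2 <- update_clustering(old, seqs, new_seqs, p90)
  n_reps <- length(unique(old$representative))
  expect_lte(alignment_count(), 1L * n_reps)
  tb <- as.data.frame(up2)
  expect_equal(tb$representative[tb$member == "NEW1"], rep1)
  expect_equal(sort(unique(tb$cluster_id)), sort(unique(old$cluster_id)))

  # dropped representative promotes the longest remaining member, same id
  drop_rep <- unique(old$representative)[2]
  cid <- old$cluster_id[old$representative == drop_rep][1]
  kept <- seqs[seqs$accession != drop_rep, ]
  up3 <- update_clustering(old, seqs, kept, p90)
  tb3 <- as.data.frame(up3)
  expect_true(cid %in% tb3$cluster_id)
  expect_false(drop_rep %in% tb3$member)
  survivors <- old$member[old$cluster_id == cid & old$member != drop_rep]
  len <- setNames(nchar(kept$residues), kept$accession)
  expect_equal(unique(tb3$representative[tb3$cluster_id == cid]),
               survivors[order(-len[survivors], survivors)][1])

  # an unrelated new sequence founds a fresh cluster with a fresh id
  novel <- protein_tbl("NOVEL", random_protein(1, 180))
  set.seed(35)
  up4 <- update_clustering(old, seqs, dplyr::bind_rows(seqs, novel), p90)
  tb4 <- as.data.frame(up4)
  new_id <- setdiff(tb4$cluster_id, old$cluster_id)
  expect_length(new_id, 1L)
  expect_match(new_id, "^uc90-1605-")
  expect_equal(tb4$member[tb4$cluster_id == new_id], "NOVEL")

  # accessions are immutable
  mut <- seqs
  mut$residues[3] <- mutate_sequence(mut$residues[3], 0.5)
  expect_error(update_clustering(old, seqs, mut, p90), "immutable")
})

test_that("every clustering operation emits a valid partition satisfying its thresholds", {
  fam <- generate_families(3, 5, 200, 0.95, fragment_prob = 0.2, seed = 13)
  seqs <- fam$sequences
  cls <- cascade(seqs)
  res <- setNames(seqs$residues, seqs$accession)
  for (nm in names(cls)) {
    tb <- as.data.frame(cls[[nm]])
    # partition: disjoint, complete, representative in members
    expect_equal(sort(tb$member), sort(seqs$accession))
    expect_equal(anyDuplicated(tb$member), 0L)
    expect_true(all(unique(tb$representative) %in% tb$member))
    # threshold soundness (fragment rule as fallback)
    params <- cluster_params(as.integer(sub("uc", "", nm)))
    for (i in seq_len(nrow(tb))) {
      if (tb$member[i] == tb$representative[i]) next
      al <- align_pair(res[[tb$member[i]]], res[[tb$representative[i]]])
      direct <- al$identity >= params$min_seq_id &&
        cov_of(al, params)
      fragment <- al$identity >= params$fragment_min_id && al$q_cov >= 0.95
      expect_true(direct || fragment)
    }
  }
})
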