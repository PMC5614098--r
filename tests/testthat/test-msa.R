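test_that("center-star MSA encodes matches, deletions and insertions in A3M", {
  # identical pair: gap-free two-row alignment
  s <- random_protein(1, 40)
  mem <- protein_tbl(c("R", "M"), c(s, s))
  m <- build_msa(mem, "R")
  expect_equal(m$aligned, c(s, s))
  expect_equal(m$n_match_columns, nchar(s))

  # deletion in the member shows as '-' at the deleted representative column
  rep_res <- "ACDEFGHIKLW"
  mem_res <- "ACDEGHIKLW"  # F deleted
  m2 <- build_msa(protein_tbl(c("R", "M"), c(rep_res, mem_res)), "R")
  expect_equal(m2$aligned[2], "ACDE-GHIKLW")

  # insertion in the member becomes lowercase and no extra match column
  m3 <- build_msa(protein_tbl(c("R", "M"),
                              c("ACDEFGHIKLW", "ACDEFWGHIKLW")), "R")
  expect_equal(m3$n_match_columns, 11L)
  expect_equal(m3$aligned[2], "ACDEFwGHIKLW")

  # n_match_columns always equals representative length
  set.seed(41)
  for (k in 1:10) {
    fam <- generate_families(1, 4, 80, 0.85, fragment_prob = 0.3, seed = k)
    rep_acc <- fam$sequences$accession[1]
    mm <- build_msa(fam$sequences, rep_acc)
    expect_equal(mm$n_match_columns,
                 nchar(fam$sequences$residues[1]))
    expect_equal(mm$accession[1], rep_acc)
  }
  expect_error(build_msa(protein_tbl(character(), character()), "R"),
               "empty")
})

test_that("consensus maximizes smoothed column probabilities deterministically", {
  s <- random_protein(1, 60)
  mem <- protein_tbl(c("A", "B", "C"), c(s, s, s))
  cons <- compute_consensus(build_msa(mem, "A"))
  expect_equal(cons$sequence, s)

  # column (A, A, R) goes to A under default pseudocount weight
  m <- msa(c("r1", "r2", "r3"), c("AWGK", "AWGK", "RWGK"))
  expect_equal(substr(compute_consensus(m)$sequence, 1, 1), "A")

  # single-sequence consensus reproduces the sequence
  one <- protein_tbl("S", random_protein(1, 30))
  expect_equal(compute_consensus(build_msa(one, "S"))$sequence, one$residues)

  # deterministic across runs
  fam <- generate_families(1, 5, 80, 0.8, seed = 3)
  mm <- build_msa(fam$sequences, fam$sequences$accession[1])
  expect_identical(compute_consensus(mm)$sequence,
                   compute_consensus(mm)$sequence)
})

test_that("summary headers rank reviewed, informative, frequent descriptions first", {
  mem <- protein_tbl(
    sprintf("P%d", 1:8),
    random_protein(8, 20),
    description = c("alpha kinase", "beta kinase", "gamma kinase",
                    "delta kinase", "epsilon kinase", "zeta kinase",
                    "eta kinase", "eta kinase"),
    source = c("unreviewed", "reviewed", "unreviewed", "unreviewed",
               "reviewed", "unreviewed", "unreviewed", "unreviewed"))
  h <- summarize_headers(mem, "uc90-1603-1", "P1")
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  expect_equal(parts[1], "uc90-1603-1")
  expect_equal(parts[2], "P1")
  expect_equal(parts[3], "n=8")
  descs <- strsplit(parts[4], "; ")[[1]]
  expect_length(descs, 5L)
  expect_equal(descs[1:2], c("beta kinase", "epsilon kinase"))
  expect_equal(descs[3], "eta kinase")  # most frequent unreviewed next
  expect_equal(parts[5], paste(mem$accession, collapse = ","))

  # all identical: one description
  mem2 <- protein_tbl(c("A", "B"), random_protein(2, 10),
                      description = "same thing")
  expect_equal(strsplit(summarize_headers(mem2, "id", "A"), "\\|")[[1]][4],
               "same thing")

  # blacklisted descriptions rank last
  mem3 <- protein_tbl(c("A", "B"), random_protein(2, 10),
                      description = c("hypothetical protein", "real kinase"))
  descs3 <- strsplit(strsplit(summarize_headers(mem3, "id", "A"),
                              "\\|")[[1]][4], "; ")[[1]]
  expect_equal(descs3, c("real kinase", "hypothetical protein"))
})

test_that("profiles reproduce matrix rows, stay finite, and ignore duplicates", {
  m <- blosum62()
  one <- protein_tbl("S", "AAAA")
  p <- build_pssm(build_msa(one, "S"))
  aa <- rownames(p$scores)
  for (j in 1:4) expect_equal(p$scores[, j], m$scores[aa, "A"])

  fam <- generate_families(1, 4, 60, 0.8, seed = 7)
  mm <- build_msa(fam$sequences, fam$sequences$accession[1])
  pp <- build_pssm(mm)
  expect_true(all(is.finite(pp$scores)))

  # duplicate row leaves the profile unchanged under sequence weighting
  dup <- msa(c(mm$accession, "dup"), c(mm$aligned, mm$aligned[2]))
  expect_equal(build_pssm(dup)$scores, pp$scores)
})

test_that("profile search retrieves members and rejects unrelated sequences", {
  fam <- generate_families(1, 5, 120, 0.9, fragment_prob = 0, seed = 8)
  mm <- build_msa(fam$sequences, fam$sequences$accession[1])
  p <- build_pssm(mm)

  hits <- profile_search(p, fam$sequences, boost_params(n_iterations = 1))
  expect_setequal(hits$t_id, fam$sequences$accession)
  expect_equal(hits$evalue, sort(hits$evalue))

  set.seed(44)
  decoys <- random_proteins_tbl(20, 120)
  hits2 <- profile_search(p, decoys, boost_params(n_iterations = 1,
                                                  search_evalue_cutoff = 1e-6))
  expect_equal(nrow(hits2), 0L)

  # hit set grows monotonically over iterations
  db <- dplyr::bind_rows(fam$sequences, decoys)
  h1 <- profile_search(p, db, boost_params(n_iterations = 1))
  h4 <- profile_search(p, db, boost_params(n_iterations = 4))
  expect_true(all(h1$t_id %in% h4$t_id))
})

test_that("diversity filtering scores records against the consensus", {
  # record identical to an all-A consensus scores the A self-score
  m <- msa(c("cons", "same", "far"), c("AAAA", "AAAA", "RRRR"))
  mat <- blosum62()
  expect_equal(mat$scores["A", "A"], 4)
  expect_equal(mat$scores["A", "R"], -1)
  f <- diversity_filter(m, "AAAA", mat, min_score_per_res = 0.0)
  expect_equal(f$accession, c("cons", "same"))  # -1.0 < 0.0 removed
  f2 <- diversity_filter(m, "AAAA", mat, min_score_per_res = 1.1)
  expect_equal(f2$accession, c("cons", "same"))  # 4.0 kept at all tiers

  # idempotence and nestedness on generated MSAs
  set.seed(45)
  for (k in 1:10) {
    fam <- generate_families(1, 6, 80, runif(1, 0.5, 0.9), seed = k)
    mm <- build_msa(fam$sequences, fam$sequences$accession[1])
    cons <- compute_consensus(mm)
    kept <- lapply(c(0.0, 0.5, 1.1), function(th)
      diversity_filter(mm, cons, mat, th)$accession)
    expect_true(all(kept[[2]] %in% kept[[1]]))
    expect_true(all(kept[[3]] %in% kept[[2]]))
    f1 <- diversity_filter(mm, cons, mat, 0.5)
    f11 <- diversity_filter(f1, cons, mat, 0.5)
    expect_identical(f1$aligned, f11$aligned)
  }
})
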