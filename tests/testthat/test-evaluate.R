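toy_ontology <- function() {
  parents <- list(root = character(), c = "root", a = "c", b = "c",
                  d = "root")
  p <- c(root = 1, c = 0.2, a = 0.1, b = 0.1, d = 0.3)
  ontology(parents, p)
}

test_that("term similarity follows the information-content formula", {
  ont <- toy_ontology()
  expect_equal(go_term_similarity("a", "a", ont), 1)
  # shared parent c with p = 0.2: 2 ln 0.2 / (ln 0.1 + ln 0.1)
  expect_equal(go_term_similarity("a", "b", ont),
               2 * log(0.2) / (log(0.1) + log(0.1)))
  expect_equal(go_term_similarity("a", "b", ont), 0.699, tolerance = 1e-3)
  # only common ancestor is the root
  expect_equal(go_term_similarity("a", "d", ont), 0)
  expect_error(go_term_similarity("a", "zzz", ont), "unknown term")

  # invalid ontologies are rejected
  expect_error(ontology(list(root = character(), x = "root"),
                        c(root = 0.5, x = 0.2)), "root")
  expect_error(ontology(list(root = character(), x = "root", y = "x"),
                        c(root = 1, x = 0.1, y = 0.5)), "non-decreasing")
  expect_error(ontology(list(root = character(), x = c("root", "y"), y = "x"),
                        c(root = 1, x = 0.1, y = 0.1)), "cycle")
})

test_that("set, keyword and name similarities match brute-force oracles", {
  ont <- toy_ontology()
  expect_equal(annotation_set_similarity("a", "a", ont), 1)
  expect_equal(annotation_set_similarity("a", "b", ont),
               go_term_similarity("a", "b", ont))
  expect_true(is.na(annotation_set_similarity(character(), "a", ont)))

  set.seed(51)
  for (k in 1:25) {
    r <- random_ontology(sample(6:14, 1))
    leafish <- setdiff(r$ont$terms, "root")
    ax <- sample(leafish, sample(1:3, 1))
    ay <- sample(leafish, sample(1:3, 1))
    got <- annotation_set_similarity(ax, ay, r$ont)
    want <- oracle_set_sim(ax, ay, r$parents, r$p)
    expect_equal(got, want)
    expect_equal(annotation_set_similarity(ay, ax, r$ont), got)  # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
    expect_equal(annotation_set_similarity(ax, ax, r$ont), 1)
  }

  expect_equal(keyword_similarity(c("k1", "k2"), c("k1", "k2")), 1)
  expect_equal(keyword_similarity(c("k1", "k2"), c("k2", "k3")), 0.5)
  expect_equal(keyword_similarity("k1", "k2"), 0)
  expect_true(is.na(keyword_similarity(character(), character())))
  set.seed(52)
  pool <- sprintf("kw%02d", 1:12)
  for (k in 1:25) {
    kx <- sample(pool, sample(1:6, 1))
    ky <- sample(pool, sample(1:6, 1))
    expect_equal(keyword_similarity(kx, ky),
                 2 * sum(kx %in% ky) / (length(kx) + length(ky)))
    expect_equal(keyword_similarity(kx, ky), keyword_similarity(ky, kx))
  }

  expect_equal(name_similarity("kinase", "kinase"), 1)
  expect_equal(name_similarity("kinase", "kinases"), 1 - 1 / 7)
  expect_equal(name_similarity("abc", "xyz"), 0)
  expect_true(is.na(name_similarity("putative kinase", "kinase")))
  expect_true(is.na(name_similarity("protein", "kinase")))
  # the word "protein" is uninformative and case is ignored
  expect_equal(name_similarity("Kinase protein", "kinase"), 1)
  set.seed(53)
  words <- c("kinase", "reductase", "zinc", "finger", "alpha", "beta")
  for (k in 1:25) {
    nx <- paste(sample(words, 2), collapse = " ")
    ny <- paste(sample(words, 2), collapse = " ")
    expect_equal(name_similarity(nx, ny),
                 1 - oracle_levenshtein(nx, ny) / max(nchar(nx), nchar(ny)))
  }
})

test_that("cluster consistency aggregates representative-vs-member similarities", {
  ont <- toy_ontology()
  mem <- protein_tbl(c("R", "M1", "M2"), random_protein(3, 20),
                     keywords = list(c("k1", "k2"), c("k1", "k2"), "k2"),
                     go_terms = list("a", "a", "a"),
                     name = c("kinase", "kinase", "kinase"))
  cc <- cluster_consistency(mem, "R", ont)
  # keyword sims vs rep: 1.0 and 2*1/3
  expect_equal(cc$keyword_worst, 2 / 3)
  expect_equal(cc$keyword_mean, (1 + 2 / 3) / 2)
  expect_equal(cc$go_mean, 1)
  expect_equal(cc$name_mean, 1)
  expect_lte(cc$keyword_worst, cc$keyword_mean)
  expect_equal(cc$average, mean(c(1, (1 + 2 / 3) / 2, 1)))

  # identically annotated: all ones
  mem2 <- protein_tbl(c("R", "M"), random_protein(2, 20),
                      keywords = list("k", "k"), go_terms = list("a", "a"),
                      name = "kinase")
  cc2 <- cluster_consistency(mem2, "R", ont)
  expect_equal(unlist(cc2[, 1:7]), setNames(rep(1, 7), names(cc2)[1:7]))

  # undefined scores are skipped, not zero-scored
  mem3 <- protein_tbl(c("R", "M1", "M2"), random_protein(3, 20),
                      keywords = list("k", "k", character()),
                      go_terms = list(character(), character(), character()),
                      name = c("kinase", "putative x", "kinase"))
  cc3 <- cluster_consistency(mem3, "R", ont)
  expect_true(is.na(cc3$go_mean))
  expect_equal(cc3$keyword_mean, 0.5)  # 1 and (2*1/3? no: {k} vs {} -> 0)
  expect_equal(cc3$name_mean, 1)       # only the defined pair counts
})

test_that("compactness equals the all-pairs oracle and samples reproducibly", {
  s <- random_protein(1, 50)
  mem <- protein_tbl(c("A", "B", "C"), c(s, s, s))
  cc <- cluster_compactness(mem)
  expect_equal(cc$mean_identity, 1)
  expect_equal(cc$worst_identity, 1)

  fam <- generate_families(1, 6, 80, 0.8, fragment_prob = 0, seed = 61)
  got <- cluster_compactness(fam$sequences)
  ids <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    ids <- c(ids, align_pair(fam$sequences$residues[i],
                             fam$sequences$residues[j])$identity)
  }
  expect_equal(got$mean_identity, mean(ids))
  expect_equal(got$worst_identity, min(ids))

  big <- generate_families(1, 15, 60, 0.9, fragment_prob = 0, seed = 62)
  a <- cluster_compactness(big$sequences, sample_size = 5, seed = 99)
  b <- cluster_compactness(big$sequences, sample_size = 5, seed = 99)
  expect_identical(a, b)
  expect_equal(a$n_sampled, 5L)
})

test_that("consistency reports aggregate to database level with worst <= mean", {
  fam <- generate_families(3, 5, 120, 0.95, seed = 63)
  ga <- generate_annotations(fam$partition, noise = 0.3, seed = 64)
  seqs <- miniclust:::annotate_proteins(fam$sequences, ga$annotations)
  cl <- cascade(seqs)$uc90
  rep <- consistency_report(cl, seqs, ga$ontology)
  expect_equal(nrow(rep), 3L)
  for (type in c("go", "keyword", "name")) {
    w <- rep[[paste0(type, "_worst")]]
    m <- rep[[paste0(type, "_mean")]]
    ok <- !is.na(w) & !is.na(m)
    expect_true(all(w[ok] <= m[ok] + 1e-12))
  }
  g <- glance(rep)
  expect_true(all(unlist(g[, -1]) >= 0 & unlist(g[, -1]) <= 1, na.rm = TRUE))

  # replacing the representative by a random member barely moves the means
  fam2 <- generate_families(10, 6, 60, 0.95, fragment_prob = 0, seed = 66)
  ga2 <- generate_annotations(fam2$partition, noise = 0.3, seed = 67)
  seqs2 <- miniclust:::annotate_proteins(fam2$sequences, ga2$annotations)
  founders <- fam2$partition$accession[!duplicated(fam2$partition$family)]
  planted <- clustering_tbl(
    representative = founders[fam2$partition$family],
    member = fam2$partition$accession)
  base_avg <- glance(consistency_report(planted, seqs2, ga2$ontology))$average
  set.seed(65)
  tb2 <- as.data.frame(planted)
  alt <- lapply(split(tb2, tb2$cluster_id), function(x) {
    cluster_consistency(seqs2[match(x$member, seqs2$accession), ],
                        sample(x$member, 1), ga2$ontology)
  })
  alt_avg <- mean(vapply(alt, function(x) x$average, numeric(1)), na.rm = TRUE)
  expect_lt(abs(alt_avg - base_avg), 0.02)
})
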