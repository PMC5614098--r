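# Independent reference implementations used to cross-check the package.
# These are written as plain, slow, loop-based R on purpose: they share no
# code with the implementation paths they verify.

# --- brute-force Smith-Waterman with affine gaps -------------------------
# Same contract as the package aligner: gap of length k costs open + k*ext,
# traceback starts at the first maximal cell in row-major order, ties
# resolved diagonal > up > left, gap closure preferred over extension.
oracle_sw <- function(q, t, scores, open = 11, ext = 1) {
  A <- strsplit(q, "")[[1]]
  B <- strsplit(t, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in target (up)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in query (left)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + scores[A[i], B[j]],
                             X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best <- max(H)
  if (best == 0) {
    return(list(score = 0, n_aligned_cols = 0, n_identical = 0,
                q_start = 0, q_end = 0, t_start = 0, t_end = 0))
  }
  hit <- which(t(H) == best)[1]  # row-major scan
  bi <- (hit - 1) %/% (m + 1) + 1
  bj <- (hit - 1) %% (m + 1) + 1
  i <- bi; j <- bj; state <- "H"
  n_al <- 0; n_id <- 0
  qs <- 0; qe <- 0; ts <- 0; te <- 0
  while (i > 1 && j > 1) {
    if (state == "H") {
      if (H[i, j] <= 0) break
      d <- H[i - 1, j - 1] + scores[A[i - 1], B[j - 1]]
      if (H[i, j] == d) {
        n_al <- n_al + 1
        if (A[i - 1] == B[j - 1]) n_id <- n_id + 1
        qs <- i - 1; ts <- j - 1
        if (qe == 0) { qe <- i - 1; te <- j - 1 }
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == X[i, j]) state <- "X"
      else state <- "Y"
    } else if (state == "X") {
      if (qe == 0) qe <- i - 1
      qs <- i - 1
      if (X[i, j] == H[i - 1, j] - open - ext) state <- "H"
      i <- i - 1
    } else {
      if (te == 0) te <- j - 1
      ts <- j - 1
      if (Y[i, j] == H[i, j - 1] - open - ext) state <- "H"
      j <- j - 1
    }
  }
  list(score = best, n_aligned_cols = n_al, n_identical = n_id,
       q_start = qs, q_end = qe, t_start = ts, t_end = te)
}

oracle_align_row <- function(q, t, m = blosum62()) {
  o <- oracle_sw(q, t, m$scores, m$gap_open, m$gap_extend)
  list(score = o$score,
       identity = if (o$n_aligned_cols) o$n_identical / o$n_aligned_cols else 0,
       q_cov = if (o$n_aligned_cols) (o$q_end - o$q_start + 1) / nchar(q) else 0,
       t_cov = if (o$n_aligned_cols) (o$t_end - o$t_start + 1) / nchar(t) else 0)
}

# --- brute-force greedy set cover ----------------------------------------
# Returns the partition as a sorted list of sorted member vectors.
oracle_set_cover <- function(ids, len, edges) {
  nbr <- setNames(rep(list(character()), length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]; b <- edges$to[k]
    if (a == b) next
    nbr[[a]] <- union(nbr[[a]], b)
    nbr[[b]] <- union(nbr[[b]], a)
  }
  uncovered <- ids
  clusters <- list()
  while (length(uncovered)) {
    gain <- vapply(uncovered, function(v)
      1L + length(intersect(nbr[[v]], uncovered)), integer(1))
    pick <- uncovered[order(-gain, -len[uncovered], uncovered)][1]
    cl <- c(pick, intersect(nbr[[pick]], uncovered))
    clusters[[length(clusters) + 1L]] <- sort(cl)
    uncovered <- setdiff(uncovered, cl)
  }
  clusters[order(vapply(clusters, `[[`, "", 1L))]
}

partition_of <- function(clustering) {
  tb <- as.data.frame(clustering)
  cl <- lapply(split(tb$member, tb$cluster_id), sort)
  unname(cl[order(vapply(cl, `[[`, "", 1L))])
}

random_graph <- function(n, p_edge = 0.3) {
  ids <- sprintf("V%02d", seq_len(n))
  len <- setNames(sample(50:200, n, replace = TRUE), ids)
  from <- character(); to <- character()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (runif(1) < p_edge) { from <- c(from, ids[i]); to <- c(to, ids[j]) }
  }
  list(vertices = tibble::tibble(id = ids, length = unname(len)),
       edges = tibble::tibble(from = from, to = to), len = len)
}

# --- brute-force ontology similarities -----------------------------------
oracle_ancestors <- function(term, parents) {
  out <- term
  queue <- parents[[term]]
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    if (!t %in% out) {
      out <- c(out, t)
      queue <- c(queue, parents[[t]])
    }
  }
  out
}

oracle_term_sim <- function(a, b, parents, p) {
  anc <- intersect(oracle_ancestors(a, parents), oracle_ancestors(b, parents))
  panc <- p[anc]
  lca <- anc[order(panc, anc)][1]
  den <- log(p[[a]]) + log(p[[b]])
  if (den == 0) 0 else 2 * log(p[[lca]]) / den
}

oracle_set_sim <- function(ax, ay, parents, p) {
  ax <- unique(ax); ay <- unique(ay)
  s1 <- 0
  for (a in ax) s1 <- s1 + max(vapply(ay, function(b)
    oracle_term_sim(a, b, parents, p), numeric(1)))
  s2 <- 0
  for (b in ay) s2 <- s2 + max(vapply(ax, function(a)
    oracle_term_sim(a, b, parents, p), numeric(1)))
  (s1 + s2) / (length(ax) + length(ay))
}

oracle_levenshtein <- function(x, y) {
  a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
  D <- matrix(0, length(a) + 1, length(b) + 1)
  D[, 1] <- 0:length(a); D[1, ] <- 0:length(b)
  for (i in seq_along(a)) for (j in seq_along(b)) {
    D[i + 1, j + 1] <- min(D[i, j + 1] + 1, D[i + 1, j] + 1,
                           D[i, j] + (a[i] != b[j]))
  }
  D[length(a) + 1, length(b) + 1]
}

# random toy ontology: a random tree with monotone probabilities
random_ontology <- function(n_terms = 12) {
  terms <- c("root", sprintf("T%02d", seq_len(n_terms - 1)))
  parents <- list(root = character())
  p <- c(root = 1)
  for (k in 2:n_terms) {
    par <- sample(terms[seq_len(k - 1)], 1)
    parents[[terms[k]]] <- par
    p[terms[k]] <- p[[par]] * runif(1, 0.3, 0.9)
  }
  list(ont = ontology(parents, p), parents = parents, p = p)
}

# --- misc fixtures --------------------------------------------------------
random_proteins_tbl <- function(n, len = 40) {
  protein_tbl(sprintf("P%03d", seq_len(n)), random_protein(n, len),
              description = sprintf("synthetic record %d", seq_len(n)))
}

# two-tier families: each base family gets a distant sister family whose
# founder sits at ~40% identity, so 90%-level clusters stay apart while the
# 30%-level set cover merges family and sister into one supercluster
hierarchical_fixture <- function(n_families = 3, members = 4, len = 200,
                                 seed = 1) {
  set.seed(seed)
  acc <- character(); res <- character(); fam <- integer(); super <- integer()
  id <- 0
  for (f in seq_len(n_families)) {
    founders <- character(2)
    founders[1] <- random_protein(1, len)
    founders[2] <- mutate_sequence(founders[1], 0.40)
    for (s in 1:2) {
      id <- id + 1
      for (j in seq_len(members)) {
        acc <- c(acc, sprintf("S%02d_F%02d_M%02d", f, s, j))
        res <- c(res, if (j == 1) founders[s]
                 else mutate_sequence(founders[s], 0.95))
        fam <- c(fam, id); super <- c(super, f)
      }
    }
  }
  list(sequences = protein_tbl(acc, res),
       partition = tibble::tibble(accession = acc, family = fam,
                                  superfamily = super))
}
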