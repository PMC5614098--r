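#' Construct an annotation ontology
#'
#' A rooted directed acyclic graph of terms with per-term annotation
#' probabilities: `p[term]` is the probability that a protein is annotated
#' with the term or any of its descendants.  Probabilities must lie in
#' (0, 1], be 1 at the root, and never decrease from child to parent.
#'
#' @param parents Named list mapping each non-root term to its parent
#'   term(s).
#' @param p Named numeric vector of annotation probabilities covering every
#'   term.
#' @return An object of class `ontology` with fields `terms`, `parents`,
#'   `p`.
#' @export
ontology <- function(parents, p) {
  terms <- union(names(parents), unlist(parents, use.names = FALSE))
  if (!all(terms %in% names(p)))
    abort("p must cover every term")
  p <- p[terms]
  if (any(p <= 0 | p > 1)) abort("probabilities must lie in (0, 1]")
  roots <- setdiff(terms, names(parents)[lengths(parents) > 0])
  if (!length(roots)) abort("ontology has no root")
  if (any(p[roots] != 1)) abort("root terms must have p = 1")
  # Kahn-style peeling: a topological order exists iff the DAG is acyclic
  remaining <- terms
  repeat {
    free <- remaining[!vapply(remaining, function(t)
      any(parents[[t]] %in% remaining), logical(1))]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining)) abort("ontology contains a cycle")
  ont <- structure(list(terms = terms, parents = parents, p = p),
                   class = "ontology")
  bad <- unlist(lapply(names(parents), function(ch)
    if (any(p[parents[[ch]]] < p[ch])) ch), use.names = FALSE)
  if (length(bad))
    abort(sprintf("p must be non-decreasing from child to parent (term %s)",
                  bad[1]))
  ont
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms\n", length(x$terms)))
  invisible(x)
}

# all ancestors of a term including itself; cycle-safe
term_ancestors <- function(term, ont) {
  if (!term %in% ont$terms) abort(sprintf("unknown term '%s'", term))
  seen <- character()
  stack <- term
  while (length(stack)) {
    t <- stack[1]; stack <- stack[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, ont$parents[[t]])
  }
  seen
}

#' Annotation-probability-based term similarity
#'
#' The information-content similarity of two ontology terms:
#' `2 log P(LCA(a, b)) / (log P(a) + log P(b))`, where the LCA is the common
#' ancestor (terms included) with the smallest annotation probability, i.e.
#' maximal information content (ties: lexicographically smallest term).
#' Equals 1 for `a == b` with informative `p(a) < 1` and 0 when the only
#' common ancestor is the root.
#'
#' @param a,b Term identifiers.
#' @param ont An [ontology].
#' @return A similarity in \[0, 1\].
#' @export
go_term_similarity <- function(a, b, ont) {
  anc <- intersect(term_ancestors(a, ont), term_ancestors(b, ont))
  if (!length(anc)) abort("terms share no common ancestor (namespaces differ?)")
  panc <- ont$p[anc]
  lca <- anc[order(panc, anc)][1]
  denom <- log(ont$p[[a]]) + log(ont$p[[b]])
  if (denom == 0) return(0)
  2 * log(ont$p[[lca]]) / denom
}

#' Similarity between two annotation sets
#'
#' Best-match averaging of term similarities: every term of one set is
#' matched to its most similar term in the other set, and the matched
#' similarities are averaged over both directions.  Symmetric, in \[0, 1\],
#' and 1 iff the sets are equal (given informative terms).
#'
#' @param a_x,a_y Character vectors of term identifiers.
#' @param ont An [ontology].
#' @return A similarity in \[0, 1\], or `NA` when either set is empty
#'   (missing annotation, not inconsistency).
#' @export
annotation_set_similarity <- function(a_x, a_y, ont) {
  a_x <- unique(a_x); a_y <- unique(a_y)
  if (!length(a_x) || !length(a_y)) return(NA_real_)
  simmat <- outer(a_x, a_y,
                  Vectorize(function(a, b) go_term_similarity(a, b, ont)))
  (sum(apply(simmat, 1, max)) + sum(apply(simmat, 2, max))) /
    (length(a_x) + length(a_y))
}

#' Keyword set similarity
#'
#' The Dice coefficient `2 |K_x n K_y| / (|K_x| + |K_y|)`: the best-match
#' averaging of [annotation_set_similarity()] under the identity kernel.
#' Keywords from non-functional categories (e.g. technical terms) should be
#' filtered out before calling.
#'
#' @param k_x,k_y Character vectors of keywords.
#' @return A similarity in \[0, 1\]; `NA` when both sets are empty.
#' @export
keyword_similarity <- function(k_x, k_y) {
  k_x <- unique(k_x); k_y <- unique(k_y)
  if (!length(k_x) && !length(k_y)) return(NA_real_)
  2 * length(intersect(k_x, k_y)) / (length(k_x) + length(k_y))
}

#' Protein name similarity
#'
#' One minus the Levenshtein edit distance between the normalized names,
#' divided by the length of the longer one.  Normalization lowercases,
#' removes the uninformative word "protein" and collapses whitespace.
#' Names starting with uncharacterized, putative, potential, probable,
#' inactive, likely or unknown carry no comparable information and yield
#' `NA`, as do names that are empty after normalization.
#'
#' @param name_x,name_y Protein name strings.
#' @return A similarity in \[0, 1\] or `NA`.
#' @export
name_similarity <- function(name_x, name_y) {
  x <- normalize_name(name_x)
  y <- normalize_name(name_y)
  if (is.na(x) || is.na(y)) return(NA_real_)
  1 - as.numeric(adist(x, y)) / max(nchar(x), nchar(y))
}

normalize_name <- function(name) {
  if (is.null(name) || is.na(name)) return(NA_character_)
  x <- tolower(trimws(name))
  stop_words <- c("uncharacterized", "putative", "potential", "probable",
                  "inactive", "likely", "unknown")
  if (any(startsWith(x, stop_words))) return(NA_character_)
  x <- gsub("\\bprotein\\b", " ", x)
  x <- trimws(gsub("\\s+", " ", x))
  if (!nzchar(x)) NA_character_ else x
}

#' Annotation consistency of one cluster
#'
#' Pairwise annotation similarities between the cluster representative and
#' every other member, for the three annotation types (ontology terms,
#' keywords, protein names).  Pairs with an undefined similarity (missing
#' annotation on either side) are skipped, not scored zero.  Reports the
#' worst (minimum) and mean similarity per type, and the cross-type average
#' of the mean scores over the types that are defined.
#'
#' @param members Protein tibble of the cluster members (with `go_terms`,
#'   `keywords`, `name` columns).
#' @param representative Representative accession.
#' @param ont An [ontology] (may be `NULL` to skip the ontology score).
#' @return One-row tibble: `go_worst`, `go_mean`, `keyword_worst`,
#'   `keyword_mean`, `name_worst`, `name_mean`, `average`, `n_pairs`.
#' @export
cluster_consistency <- function(members, representative, ont = NULL) {
  if (nrow(members) < 2) abort("consistency needs a cluster of size >= 2")
  rep_row <- members[members$accession == representative, ]
  others <- members[members$accession != representative, ]
  sims <- function(f) vapply(seq_len(nrow(others)), f, numeric(1))
  go <- if (is.null(ont)) rep(NA_real_, nrow(others)) else
    sims(function(i) annotation_set_similarity(rep_row$go_terms[[1]],
                                               others$go_terms[[i]], ont))
  kw <- sims(function(i) keyword_similarity(rep_row$keywords[[1]],
                                            others$keywords[[i]]))
  nm <- sims(function(i) name_similarity(rep_row$name[1], others$name[i]))
  agg <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) c(NA_real_, NA_real_) else c(min(x), mean(x))
  }
  g <- agg(go); k <- agg(kw); n <- agg(nm)
  means <- c(g[2], k[2], n[2])
  tibble(go_worst = g[1], go_mean = g[2],
         keyword_worst = k[1], keyword_mean = k[2],
         name_worst = n[1], name_mean = n[2],
         average = if (all(is.na(means))) NA_real_ else mean(means, na.rm = TRUE),
         n_pairs = nrow(others))
}

#' Consistency report over a clustering
#'
#' Applies [cluster_consistency()] to every cluster with at least two
#' members and aggregates to database level.
#'
#' @param clustering A `miniclust_clustering`.
#' @param seqs Annotated protein tibble covering all members.
#' @param ont An [ontology] or `NULL`.
#' @return A tibble of class `consistency_report`, one row per non-singleton
#'   cluster; `glance()` gives the database-level means.
#' @export
consistency_report <- function(clustering, seqs, ont = NULL) {
  tb <- as_tibble(clustering)
  per <- lapply(split(tb, tb$cluster_id), function(cl) {
    if (nrow(cl) < 2) return(NULL)
    members <- seqs[match(cl$member, seqs$accession), ]
    row <- cluster_consistency(members, cl$representative[1], ont)
    dplyr::bind_cols(tibble(cluster_id = cl$cluster_id[1],
                            representative = cl$representative[1]), row)
  })
  out <- dplyr::bind_rows(per)
  class(out) <- unique(c("consistency_report", class(out)))
  out
}

#' @rdname consistency_report
#' @param x A `consistency_report`.
#' @param ... Unused.
#' @export
glance.consistency_report <- function(x, ...) {
  mean_of <- function(col) mean(x[[col]], na.rm = TRUE)
  tibble(n_clusters = nrow(x),
         go_worst = mean_of("go_worst"), go_mean = mean_of("go_mean"),
         keyword_worst = mean_of("keyword_worst"),
         keyword_mean = mean_of("keyword_mean"),
         name_worst = mean_of("name_worst"), name_mean = mean_of("name_mean"),
         average = mean_of("average"))
}

#' Cluster compactness by pairwise sequence identity
#'
#' Mean and worst pairwise sequence identity between the members of a
#' cluster, computed by local alignment over all member pairs; clusters
#' larger than `sample_size` are represented by a seeded uniform sample of
#' `sample_size` members.
#'
#' @param members Protein tibble of the cluster members (size >= 2).
#' @param sample_size Maximum number of members aligned all-vs-all.
#' @param seed Integer seed making the sampling reproducible.
#' @param m Substitution matrix.
#' @return One-row tibble: `mean_identity`, `worst_identity`, `n_sampled`.
#' @export
cluster_compactness <- function(members, sample_size = 10, seed = 1,
                                m = blosum62()) {
  if (nrow(members) < 2) abort("compactness needs a cluster of size >= 2")
  if (nrow(members) > sample_size) {
    members <- with_local_seed(seed,
      members[sample(nrow(members), sample_size), ])
  }
  n <- nrow(members)
  ids <- numeric()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      al <- align_pair(members$residues[i], members$residues[j], m)
      ids <- c(ids, al$identity)
    }
  }
  tibble(mean_identity = mean(ids), worst_identity = min(ids), n_sampled = n)
}

#' Term annotation probabilities from a corpus
#'
#' Computes `P(a)` as the add-one-smoothed fraction of proteins annotated
#' with term `a` or any of its descendants: `(n_a + 1) / (N + 1)` where
#' `n_a` counts proteins whose annotation set, propagated to ancestors,
#' contains `a`.  The root gets probability 1 and unobserved terms stay
#' positive, as the ontology contract requires.
#'
#' @param go_terms List column (or list) of per-protein term sets.
#' @param parents Named parent list as in [ontology()].
#' @return An [ontology] with corpus-derived probabilities.
#' @export
ontology_from_corpus <- function(go_terms, parents) {
  terms <- union(names(parents), unlist(parents, use.names = FALSE))
  dummy <- ontology(parents, setNames(rep(1, length(terms)), terms))
  n <- length(go_terms)
  counts <- setNames(rep(0L, length(terms)), terms)
  for (ann in go_terms) {
    anc <- unique(unlist(lapply(ann, term_ancestors, ont = dummy)))
    counts[anc] <- counts[anc] + 1L
  }
  ontology(parents, (counts + 1) / (n + 1))
}
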