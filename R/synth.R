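#' Random protein sequences
#'
#' Uniform-random sequences over the 20 standard residues.  Independent
#' random sequences of a few hundred residues align at well under 30%
#' identity with overwhelming probability, which makes them suitable
#' between-family backgrounds for clustering experiments.
#'
#' @param n Number of sequences.
#' @param len Length (recycled).
#' @return Character vector of residue strings.
#' @export
random_protein <- function(n, len) {
  len <- rep_len(len, n)
  aa <- names(aa_background())
  vapply(len, function(L) paste0(sample(aa, L, replace = TRUE),
                                 collapse = ""), "")
}

#' Mutate a sequence to an exact target identity
#'
#' Substitutes residues at positions drawn without replacement so that the
#' realized column-wise identity to the parent is exactly
#' `round(len * target_identity) / len`.  Replacement residues are drawn
#' from the BLOSUM62-derived exchange probabilities of the original residue
#' (excluding the residue itself), mimicking homologous divergence rather
#' than uniform noise.
#'
#' @param seq Residue string.
#' @param target_identity Fraction in (0, 1].
#' @return The mutated residue string.
#' @export
mutate_sequence <- function(seq, target_identity) {
  stopifnot(target_identity > 0, target_identity <= 1)
  chars <- strsplit(seq, "")[[1]]
  len <- length(chars)
  n_mut <- len - round(len * target_identity)
  if (n_mut == 0) return(seq)
  pos <- sample(len, n_mut)
  xp <- exchange_probs()
  aa <- rownames(xp)
  for (i in pos) {
    b <- chars[i]
    pr <- if (b %in% colnames(xp)) xp[, b] else setNames(rep(1, 20), aa)
    pr[b] <- 0
    chars[i] <- sample(aa, 1, prob = pr)
  }
  paste0(chars, collapse = "")
}

#' Generate planted families of homologous sequences
#'
#' Emulates the structure clustering is meant to recover: each family grows
#' from an independent uniform-random founder sequence; the founder itself
#' is member 1 (the full-length family anchor), and every further member is
#' mutated to the target within-family identity.  With probability
#' `fragment_prob` a non-founder member is additionally truncated to a
#' uniform 30-60% prefix or suffix, exercising the fragment-absorption
#' rule.  Deterministic under `seed`.
#'
#' @param n_families,members_per_family,seq_len Family layout.
#' @param within_identity Identity of each member to its founder.
#' @param fragment_prob Probability that a non-founder member is a
#'   fragment.
#' @param seed Integer seed.
#' @return A list with `sequences` (protein tibble, accessions
#'   `F<i>_M<j>`) and `partition` (tibble `accession`, `family`).
#' @export
generate_families <- function(n_families = 3, members_per_family = 5,
                              seq_len = 200, within_identity = 0.95,
                              fragment_prob = 0.1, seed = 42) {
  stopifnot(n_families >= 1, members_per_family >= 1, seq_len >= 10,
            within_identity > 0, within_identity <= 1)
  with_local_seed(seed, {
    acc <- character(); res <- character(); fam <- integer()
    for (f in seq_len(n_families)) {
      founder <- random_protein(1, seq_len)
      for (j in seq_len(members_per_family)) {
        s <- if (j == 1) founder else mutate_sequence(founder, within_identity)
        if (j > 1 && runif(1) < fragment_prob) {
          keep <- round(nchar(s) * runif(1, 0.3, 0.6))
          s <- if (runif(1) < 0.5) substr(s, 1, keep)
               else substr(s, nchar(s) - keep + 1, nchar(s))
        }
        acc <- c(acc, sprintf("F%02d_M%02d", f, j))
        res <- c(res, s)
        fam <- c(fam, f)
      }
    }
    list(sequences = protein_tbl(acc, res,
                                 description = sprintf("family %d member", fam)),
         partition = tibble(accession = acc, family = fam))
  })
}

#' Generate a toy ontology and an annotated corpus
#'
#' Builds a balanced term tree of the given depth and branching factor with
#' annotation probabilities decreasing geometrically with depth
#' (`branching^-depth`), then annotates the proteins of a planted partition:
#' all members of a family share a randomly chosen leaf term, a keyword set
#' and a protein name, each perturbed independently per protein with
#' probability `noise` (sibling-leaf swap; keyword drop or addition; a
#' one-character name typo).  Deterministic under `seed`.
#'
#' @param partition Tibble with `accession` and `family` (as returned by
#'   [generate_families()]).
#' @param depth,branching Tree layout (depth >= 2).
#' @param noise Per-protein perturbation probability.
#' @param seed Integer seed.
#' @return A list with `ontology` (probabilities derived from the generated
#'   corpus via [ontology_from_corpus()]) and `annotations` (protein-shaped
#'   tibble with `accession`, `go_terms`, `keywords`, `name`).
#' @export
generate_annotations <- function(partition, depth = 3, branching = 3,
                                 noise = 0, seed = 42) {
  stopifnot(depth >= 2, branching >= 2, noise >= 0, noise <= 1)
  parents <- list(root = character())
  level <- "root"
  for (d in seq_len(depth)) {
    nxt <- character()
    for (t in level) {
      kids <- sprintf("%s.%d", t, seq_len(branching))
      for (k in kids) parents[[k]] <- t
      nxt <- c(nxt, kids)
    }
    level <- nxt
  }
  leaves <- level
  kw_pool <- sprintf("kw%02d", 1:30)
  name_words <- c("kinase", "transferase", "hydrolase", "transporter",
                  "receptor", "synthase", "ligase", "reductase", "binding",
                  "membrane", "ribosomal", "zinc", "finger", "domain")
  with_local_seed(seed, {
    fams <- sort(unique(partition$family))
    fam_leaf <- sample(leaves, length(fams), replace = length(leaves) < length(fams))
    fam_kw <- lapply(fams, function(f) sample(kw_pool, 3))
    fam_name <- vapply(fams, function(f)
      paste(sample(name_words, 2), collapse = " "), "")
    sibling <- function(leaf) {
      sib <- setdiff(sprintf("%s.%d", parents[[leaf]], seq_len(branching)), leaf)
      sample(sib, 1)
    }
    typo <- function(x) {
      i <- sample(nchar(x), 1)
      substr(x, i, i) <- sample(letters, 1)
      x
    }
    n <- nrow(partition)
    go <- vector("list", n); kw <- vector("list", n); nm <- character(n)
    for (i in seq_len(n)) {
      f <- match(partition$family[i], fams)
      leaf <- fam_leaf[f]; keys <- fam_kw[[f]]; name <- fam_name[f]
      if (runif(1) < noise) leaf <- sibling(leaf)
      if (runif(1) < noise) {
        keys <- if (runif(1) < 0.5 && length(keys) > 1) keys[-sample(length(keys), 1)]
                else union(keys, sample(kw_pool, 1))
      }
      if (runif(1) < noise) name <- typo(name)
      go[[i]] <- leaf; kw[[i]] <- keys; nm[i] <- name
    }
    annotations <- tibble(accession = partition$accession,
                          go_terms = go, keywords = kw, name = nm)
    list(ontology = ontology_from_corpus(go, parents),
         annotations = annotations)
  })
}

# attach generated annotations to a protein tibble
annotate_proteins <- function(seqs, annotations) {
  i <- match(seqs$accession, annotations$accession)
  seqs$go_terms <- annotations$go_terms[i]
  seqs$keywords <- annotations$keywords[i]
  seqs$name <- annotations$name[i]
  seqs
}

#' Generate random domain matches on a consensus sequence
#'
#' Fabricates valid database matches with random non-degenerate spans on
#' the consensus and log-uniform E-values, for exercising the annotation
#' acceptance and transfer machinery.  Deterministic under `seed`.
#'
#' @param consensus A `consensus_record` or plain string.
#' @param n Number of matches.
#' @param evalue_range Range of the log-uniform E-value draw.
#' @param query_id Query identifier written into the records.
#' @param database Database label.
#' @param seed Integer seed.
#' @return An annotation tibble ([annotation_tbl()]).
#' @export
generate_domain_matches <- function(consensus, n, evalue_range = c(1e-10, 0.1),
                                    query_id = "consensus", database = "pfam",
                                    seed = 42) {
  stopifnot(n >= 0)
  L <- nchar(consensus_seq(consensus))
  if (!n) {
    return(annotation_tbl(character(), character(), integer(), integer(),
                          integer(), integer(), integer(), integer(),
                          numeric(), character()))
  }
  with_local_seed(seed, {
    span <- pmin(L, pmax(10L, round(runif(n, 0.1, 0.8) * L)))
    q_start <- vapply(span, function(s) sample(L - s + 1L, 1L), integer(1))
    t_len <- span + sample(0:20, n, replace = TRUE)
    t_start <- vapply(t_len - span + 1L, function(k) sample(k, 1L), integer(1))
    ev <- exp(runif(n, log(evalue_range[1]), log(evalue_range[2])))
    annotation_tbl(query_id = rep(query_id, n),
                   target_id = sprintf("PF%05d", seq_len(n)),
                   q_start = q_start, q_end = q_start + span - 1L, q_len = L,
                   t_start = t_start, t_end = t_start + span - 1L,
                   t_len = t_len, evalue = ev, database = database)
  })
}
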