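#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format distributed with BLAST (a comment
#' header, a row of column letters, then one labelled row per residue) and
#' attaches affine gap penalties, producing the scoring model used by all
#' alignment steps.
#'
#' @param path Path to an NCBI-format matrix file.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.  Defaults 11/1, the standard pairing with
#'   BLOSUM62.
#' @return An object of class `substitution_matrix`: a list with `scores`
#'   (symmetric integer matrix with residue dimnames), `gap_open`,
#'   `gap_extend`, and `alphabet`.
#' @export
read_score_matrix <- function(path, gap_open = 11, gap_extend = 1) {
  stopifnot(file.exists(path), gap_open > 0, gap_extend > 0)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  scores <- matrix(
    vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))),
    nrow = length(cols),
    dimnames = list(cols, vapply(rows, `[[`, "", 1L))
  )
  scores <- t(scores)
  if (!isTRUE(all.equal(scores, t(scores))))
    abort("substitution matrix must be symmetric")
  new_substitution_matrix(scores, gap_open, gap_extend)
}

new_substitution_matrix <- function(scores, gap_open, gap_extend) {
  structure(
    list(scores = scores, gap_open = gap_open, gap_extend = gap_extend,
         alphabet = rownames(scores)),
    class = "substitution_matrix"
  )
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat(sprintf("<substitution_matrix> %d letters, gap open %g, extend %g\n",
              length(x$alphabet), x$gap_open, x$gap_extend))
  invisible(x)
}

#' The BLOSUM62 scoring model
#'
#' Loads the bundled BLOSUM62 matrix (NCBI text format) with the standard
#' affine gap penalties 11/1.  The object is cached for the session.
#'
#' @param gap_open,gap_extend Override the default gap penalties.
#' @return A `substitution_matrix`.
#' @export
blosum62 <- function(gap_open = 11, gap_extend = 1) {
  key <- sprintf("blosum62_%g_%g", gap_open, gap_extend)
  if (is.null(the[[key]])) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "miniclust")
    the[[key]] <- read_score_matrix(path, gap_open, gap_extend)
  }
  the[[key]]
}

# Robinson-Robinson amino acid background frequencies
aa_background <- function() {
  c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
    Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
    L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
    S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
}

# Conditional exchange probabilities q(a | b) derived from the matrix via
# q(a|b) proportional to p_a * exp(lambda_u * s(a,b)), with lambda_u the
# ungapped BLOSUM62 scale (0.3176 per score unit).  Rows sum to 1.  Used for
# profile pseudocounts and for homolog-like substitution sampling.
exchange_probs <- function(m = blosum62(), lambda_u = 0.3176) {
  key <- sprintf("xprob_%g", lambda_u)
  if (is.null(the[[key]])) {
    aa <- names(aa_background())
    s <- m$scores[aa, aa]
    q <- exp(lambda_u * s) * aa_background()[col(s)]
    q <- q / rowSums(q)
    dimnames(q) <- list(aa, aa)
    the[[key]] <- t(q)  # column b gives q(. | b)
  }
  the[[key]]
}
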