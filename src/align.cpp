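#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps over a precomputed
// position-pair score matrix S (n_q x n_t).  A gap of length k costs
// gap_open + k * gap_extend.  Traceback is fully deterministic:
//   * start cell: maximal H, ties broken by smallest query index, then
//     smallest target index (the first maximum in row-major order);
//   * step choice on score ties: diagonal > up (gap in target) > left
//     (gap in query); gap closure is preferred over gap extension.
// qcodes/tcodes are residue codes used only for identity counting.
// [[Rcpp::export]]
List sw_dp(NumericMatrix S, IntegerVector qcodes, IntegerVector tcodes,
           double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // full matrices: desk-scale inputs only
  NumericMatrix H(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { Ix(0, j) = NEG; Iy(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { Ix(i, 0) = NEG; Iy(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double ix = H(i - 1, j) - gap_open - gap_extend;
      double ix2 = Ix(i - 1, j) - gap_extend;
      Ix(i, j) = ix >= ix2 ? ix : ix2;
      double iy = H(i, j - 1) - gap_open - gap_extend;
      double iy2 = Iy(i, j - 1) - gap_extend;
      Iy(i, j) = iy >= iy2 ? iy : iy2;
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double h = 0.0;
      if (d > h) h = d;
      if (Ix(i, j) > h) h = Ix(i, j);
      if (Iy(i, j) > h) h = Iy(i, j);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> pq, pt;  // reversed path; 0 marks a gap
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 = H, 1 = Ix, 2 = Iy
    while (i > 0 && j > 0) {
      if (state == 0) {
        if (H(i, j) <= 0.0) break;
        double d = H(i - 1, j - 1) + S(i - 1, j - 1);
        if (H(i, j) == d) { pq.push_back(i); pt.push_back(j); --i; --j; }
        else if (H(i, j) == Ix(i, j)) state = 1;
        else state = 2;
      } else if (state == 1) {
        pq.push_back(i); pt.push_back(0);
        if (Ix(i, j) == H(i - 1, j) - gap_open - gap_extend) state = 0;
        --i;
      } else {
        pq.push_back(0); pt.push_back(j);
        if (Iy(i, j) == H(i, j - 1) - gap_open - gap_extend) state = 0;
        --j;
      }
    }
  }
  const int L = pq.size();
  IntegerVector path_q(L), path_t(L);
  int n_aligned = 0, n_ident = 0;
  int q_start = 0, q_end = 0, t_start = 0, t_end = 0;
  for (int k = 0; k < L; ++k) {
    path_q[k] = pq[L - 1 - k];
    path_t[k] = pt[L - 1 - k];
    if (path_q[k] > 0 && path_t[k] > 0) {
      ++n_aligned;
      if (qcodes[path_q[k] - 1] == tcodes[path_t[k] - 1]) ++n_ident;
    }
    if (path_q[k] > 0) { if (q_start == 0) q_start = path_q[k]; q_end = path_q[k]; }
    if (path_t[k] > 0) { if (t_start == 0) t_start = path_t[k]; t_end = path_t[k]; }
  }
  return List::create(
    _["score"] = best, _["q_start"] = q_start, _["q_end"] = q_end,
    _["t_start"] = t_start, _["t_end"] = t_end,
    _["n_aligned_cols"] = n_aligned, _["n_identical"] = n_ident,
    _["path_q"] = path_q, _["path_t"] = path_t);
}

// 64-bit FNV-1a hash, reported as a 16-character hex string (R has no
// native unsigned 64-bit integer).  Stable across runs and platforms.
// [[Rcpp::export]]
CharacterVector fnv1a64(CharacterVector x) {
  const uint64_t prime = 1099511628211ULL;
  CharacterVector out(x.size());
  char buf[17];
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint64_t h = 14695981039346656037ULL;
    const char *s = CHAR(STRING_ELT(x, i));
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= prime;
    }
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
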