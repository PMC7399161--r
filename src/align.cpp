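#include <Rcpp.h>
using namespace Rcpp;

static const double NEG = -1e30;

// Smith-Waterman of an integer-coded protein (0..19; -1 = X) against a
// position-specific score matrix (rows = profile columns, cols = 20
// residues). Affine gaps on both sides. X scores 0 at every column.
static double sw_pssm(const int* seq, int n, const NumericMatrix& pssm,
                      double gap_open, double gap_ext) {
  const int m = pssm.nrow();
  const double* P = &pssm(0, 0);  // column-major: residue a, column j -> P[a*m + j]
  std::vector<double> pM(m + 1, 0.0), pIx(m + 1, NEG), pIy(m + 1, NEG);
  std::vector<double> cM(m + 1, 0.0), cIx(m + 1, NEG), cIy(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cM[0] = 0.0; cIx[0] = NEG; cIy[0] = NEG;
    const int a = seq[i - 1];
    const double* col = (a >= 0) ? P + (size_t)a * m : nullptr;
    double iy_prev = NEG;  // cIy[j-1]
    double cm_prev = 0.0;  // cM[j-1]
    for (int j = 1; j <= m; ++j) {
      const double s = col ? col[j - 1] : 0.0;
      double diag = pM[j - 1];
      if (pIx[j - 1] > diag) diag = pIx[j - 1];
      if (pIy[j - 1] > diag) diag = pIy[j - 1];
      if (diag < 0.0) diag = 0.0;
      const double cm = s + diag;
      double ix = pM[j] - gap_open;
      const double ix2 = pIx[j] - gap_ext;
      if (ix2 > ix) ix = ix2;
      double iy = cm_prev - gap_open;
      const double iy2 = iy_prev - gap_ext;
      if (iy2 > iy) iy = iy2;
      cM[j] = cm; cIx[j] = ix; cIy[j] = iy;
      cm_prev = cm; iy_prev = iy;
      if (cm > best) best = cm;
    }
    std::swap(pM, cM); std::swap(pIx, cIx); std::swap(pIy, cIy);
  }
  return best;
}

// [[Rcpp::export(name = ".pssm_local_score")]]
double pssm_local_score_cpp(IntegerVector seq, NumericMatrix pssm,
                            double gap_open, double gap_ext) {
  if (seq.size() == 0) return 0.0;
  return sw_pssm(&seq[0], seq.size(), pssm, gap_open, gap_ext);
}

// Batch scoring of equal-length sequences (rows of a matrix); used for the
// within-sequence shuffle null.
// [[Rcpp::export(name = ".pssm_local_scores_batch")]]
NumericVector pssm_local_scores_batch_cpp(IntegerMatrix seqs, NumericMatrix pssm,
                                          double gap_open, double gap_ext) {
  const int k = seqs.nrow(), n = seqs.ncol();
  NumericVector out(k);
  std::vector<int> buf(n);
  for (int r = 0; r < k; ++r) {
    for (int c = 0; c < n; ++c) buf[c] = seqs(r, c);
    out[r] = n > 0 ? sw_pssm(buf.data(), n, pssm, gap_open, gap_ext) : 0.0;
  }
  return out;
}

// Banded semi-global alignment of integer-coded nucleotide vectors: the
// query `a` is aligned end-to-end, gaps in the target `b` before/after the
// aligned region are free and excluded from the reported alignment length.
// The band is widened automatically to cover the length difference.
// Returns c(n_match, alignment_length).
// [[Rcpp::export(name = ".banded_global_stats")]]
IntegerVector banded_global_stats_cpp(IntegerVector a, IntegerVector b, int band,
                                      double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  const int d_lo = std::min(0, m - n) - band;
  const int d_hi = std::max(0, m - n) + band;
  const int W = d_hi - d_lo + 1;
  // score[i][j - i - d_lo], traceback: 0 diag, 1 up (gap in b), 2 left (gap in a)
  std::vector<double> prev(W, NEG), cur(W, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);
  for (int j = 0; j <= m; ++j) {
    int off = j - 0 - d_lo;
    if (off < 0 || off >= W) continue;
    prev[off] = 0.0;  // leading target bases are free
    tb[off] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    const int jlo = std::max(0, i + d_lo), jhi = std::min(m, i + d_hi);
    for (int j = jlo; j <= jhi; ++j) {
      const int off = j - i - d_lo;
      double s = NEG; unsigned char t = 0;
      if (j == 0) {
        s = i * gap; t = 1;
      } else {
        const int offd = j - i - d_lo;           // same offset in prev row for diag
        if (prev[offd] > NEG / 2) {
          s = prev[offd] + (a[i - 1] == b[j - 1] ? match : mismatch);
          t = 0;
        }
        const int offu = j - (i - 1) - d_lo;     // up: (i-1, j)
        if (offu >= 0 && offu < W && prev[offu] > NEG / 2 && prev[offu] + gap > s) {
          s = prev[offu] + gap; t = 1;
        }
        if (off - 1 >= 0 && cur[off - 1] > NEG / 2 && cur[off - 1] + gap > s) {
          s = cur[off - 1] + gap; t = 2;
        }
      }
      cur[off] = s;
      tb[(size_t)i * W + off] = t;
    }
    std::swap(prev, cur);
  }
  // best cell in the last query row: trailing target bases are free
  int jbest = -1; double sbest = NEG;
  for (int j = std::max(0, n + d_lo); j <= std::min(m, n + d_hi); ++j) {
    const int off = j - n - d_lo;
    if (prev[off] > sbest) { sbest = prev[off]; jbest = j; }
  }
  int i = n, j = (jbest < 0) ? m : jbest, nmatch = 0, alen = 0;
  while (i > 0) {
    const int off = j - i - d_lo;
    unsigned char t = (off >= 0 && off < W) ? tb[(size_t)i * W + off] : 1;
    if (t == 0 && j > 0) {
      if (a[i - 1] == b[j - 1]) ++nmatch;
      --i; --j;
    } else if (t == 1) {
      --i;
    } else if (j > 0) {
      --j;
    } else {
      --i;
    }
    ++alen;
  }
  return IntegerVector::create(nmatch, alen);
}
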