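#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps.
// A gap of length L costs gap_open + L * gap_ext (BLAST convention).
// Only the optimal score is needed downstream; two rolling rows keep
// memory at O(min(n, m)).
// [[Rcpp::export(name = ".sw_score")]]
int sw_score(const std::string& query, const std::string& subject,
             int match, int mismatch, int gap_open, int gap_ext) {
  const int n = (int)query.size(), m = (int)subject.size();
  if (n == 0 || m == 0) return 0;
  const int NEG = -1000000000;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG), Hprev(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    std::swap(H, Hprev);
    H[0] = 0;
    int F = NEG; // gap in subject (vertical) for current row
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_ext, Hprev[j] - gap_open - gap_ext);
      F = std::max(F - gap_ext, H[j - 1] - gap_open - gap_ext);
      int diag = Hprev[j - 1] +
        (query[i - 1] == subject[j - 1] ? match : mismatch);
      int h = diag;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Hamming distance from one reference to each sequence in a vector.
// Length mismatch yields NA.
// [[Rcpp::export(name = ".hamming_to_ref")]]
IntegerVector hamming_to_ref(const std::string& ref,
                             const CharacterVector& seqs) {
  const int n = seqs.size();
  const size_t L = ref.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if (std::strlen(s) != L) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t k = 0; k < L; ++k) if (s[k] != ref[k]) ++d;
    out[i] = d;
  }
  return out;
}

// For each sequence, the number of OTHER sequences of identical length
// at Hamming distance in [1, limit - 1] ("differing by fewer than
// `limit` bases"). Comparison bails out once `limit` differences are
// seen. Identical duplicates (distance 0) are not counted.
// [[Rcpp::export(name = ".neighbor_counts_under")]]
IntegerVector neighbor_counts_under(const CharacterVector& seqs, int limit) {
  const int n = seqs.size();
  IntegerVector out(n);
  std::vector<const char*> p(n);
  std::vector<size_t> len(n);
  for (int i = 0; i < n; ++i) {
    p[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = std::strlen(p[i]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (len[i] != len[j]) continue;
      int d = 0;
      const char *a = p[i], *b = p[j];
      for (size_t k = 0; k < len[i]; ++k) {
        if (a[k] != b[k] && ++d >= limit) break;
      }
      if (d >= 1 && d < limit) { ++out[i]; ++out[j]; }
    }
  }
  return out;
}

// Full pairwise Hamming matrix for equal-length sequences.
// [[Rcpp::export(name = ".hamming_matrix")]]
IntegerMatrix hamming_matrix(const CharacterVector& seqs) {
  const int n = seqs.size();
  IntegerMatrix out(n, n);
  std::vector<const char*> p(n);
  size_t L = n ? std::strlen(CHAR(STRING_ELT(seqs, 0))) : 0;
  for (int i = 0; i < n; ++i) {
    p[i] = CHAR(STRING_ELT(seqs, i));
    if (std::strlen(p[i]) != L)
      stop("hamming_matrix: sequences must share one length");
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0;
      for (size_t k = 0; k < L; ++k) if (p[i][k] != p[j][k]) ++d;
      out(i, j) = d; out(j, i) = d;
    }
  }
  return out;
}

// Apply per-copy substitutions to a parent sequence. k_per_copy gives
// the number of substitutions in each copy; positions (1-based) and
// bases are flattened in copy order. Returns one string per copy.
// [[Rcpp::export(name = ".apply_substitutions")]]
CharacterVector apply_substitutions(const std::string& parent,
                                    const IntegerVector& k_per_copy,
                                    const IntegerVector& positions,
                                    const CharacterVector& bases) {
  const int n = k_per_copy.size();
  CharacterVector out(n);
  std::string buf;
  int off = 0;
  for (int i = 0; i < n; ++i) {
    buf = parent;
    for (int k = 0; k < k_per_copy[i]; ++k, ++off) {
      int pos = positions[off] - 1;
      buf[pos] = CHAR(STRING_ELT(bases, off))[0];
    }
    out[i] = buf;
  }
  return out;
}
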