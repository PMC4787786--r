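#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Shared dynamic-programming kernels for the pipeline's three alignment modes.
// Scoring is linear-gap (match/mismatch/gap); wildcard characters ('N' for
// nucleotides, 'X' for translated residues) mismatch everything, including
// themselves. Traceback tie-break is fixed everywhere: diagonal > up > left,
// where "up" consumes a character of the first (row) sequence.

static inline bool is_wild(char c, const std::string &wild) {
  return wild.find(c) != std::string::npos;
}

static inline int pair_score(char a, char b, int match, int mismatch,
                             const std::string &wild) {
  if (is_wild(a, wild) || is_wild(b, wild)) return mismatch;
  return (a == b) ? match : mismatch;
}

struct TraceStats {
  int matches;
  int columns;
};

// Walk a traceback matrix from (i, j) until a stop cell, accumulating
// match/column counts. tb codes: 0 stop, 1 diag, 2 up, 3 left.
static TraceStats walk_traceback(const std::vector<unsigned char> &tb,
                                 const std::string &a, const std::string &b,
                                 int n_col, int i, int j, int match,
                                 int mismatch, const std::string &wild,
                                 int *a_start, int *b_start) {
  TraceStats st = {0, 0};
  while (true) {
    unsigned char mv = tb[(size_t)i * n_col + j];
    if (mv == 0) break;
    if (mv == 1) {
      st.columns++;
      if (!is_wild(a[i - 1], wild) && !is_wild(b[j - 1], wild) &&
          a[i - 1] == b[j - 1])
        st.matches++;
      i--; j--;
    } else if (mv == 2) {
      st.columns++;
      i--;
    } else {
      st.columns++;
      j--;
    }
  }
  if (a_start) *a_start = i + 1;
  if (b_start) *b_start = j + 1;
  return st;
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, int match, int mismatch,
                      int gap, std::string wild) {
  int m = a.size(), n = b.size();
  int n_col = n + 1;
  std::vector<int> s((size_t)(m + 1) * n_col);
  std::vector<unsigned char> tb((size_t)(m + 1) * n_col, 0);
  s[0] = 0;
  for (int i = 1; i <= m; i++) { s[(size_t)i * n_col] = i * gap; tb[(size_t)i * n_col] = 2; }
  for (int j = 1; j <= n; j++) { s[j] = j * gap; tb[j] = 3; }
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      int d = s[(size_t)(i - 1) * n_col + (j - 1)] +
              pair_score(a[i - 1], b[j - 1], match, mismatch, wild);
      int u = s[(size_t)(i - 1) * n_col + j] + gap;
      int l = s[(size_t)i * n_col + (j - 1)] + gap;
      int best; unsigned char mv;
      if (d >= u && d >= l) { best = d; mv = 1; }
      else if (u >= l)      { best = u; mv = 2; }
      else                  { best = l; mv = 3; }
      s[(size_t)i * n_col + j] = best;
      tb[(size_t)i * n_col + j] = mv;
    }
  }
  TraceStats st = walk_traceback(tb, a, b, n_col, m, n, match, mismatch, wild,
                                 nullptr, nullptr);
  double identity = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
  return List::create(_["score"] = s[(size_t)m * n_col + n],
                      _["matches"] = st.matches, _["columns"] = st.columns,
                      _["identity"] = identity);
}

// Semi-global: the read (first argument) is aligned end to end; gaps hanging
// off either end of the reference are free. Columns are counted over the
// read-spanning part of the alignment only.
// [[Rcpp::export]]
List cpp_align_overlap(std::string read, std::string ref, int match,
                       int mismatch, int gap, std::string wild) {
  int m = read.size(), n = ref.size();
  int n_col = n + 1;
  std::vector<int> s((size_t)(m + 1) * n_col);
  std::vector<unsigned char> tb((size_t)(m + 1) * n_col, 0);
  for (int j = 0; j <= n; j++) { s[j] = 0; tb[j] = 0; }
  for (int i = 1; i <= m; i++) { s[(size_t)i * n_col] = i * gap; tb[(size_t)i * n_col] = 2; }
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      int d = s[(size_t)(i - 1) * n_col + (j - 1)] +
              pair_score(read[i - 1], ref[j - 1], match, mismatch, wild);
      int u = s[(size_t)(i - 1) * n_col + j] + gap;
      int l = s[(size_t)i * n_col + (j - 1)] + gap;
      int best; unsigned char mv;
      if (d >= u && d >= l) { best = d; mv = 1; }
      else if (u >= l)      { best = u; mv = 2; }
      else                  { best = l; mv = 3; }
      s[(size_t)i * n_col + j] = best;
      tb[(size_t)i * n_col + j] = mv;
    }
  }
  int best_j = 0, best_score = s[(size_t)m * n_col];
  for (int j = 1; j <= n; j++) {
    if (s[(size_t)m * n_col + j] > best_score) {
      best_score = s[(size_t)m * n_col + j];
      best_j = j;
    }
  }
  int ref_start = 0;
  TraceStats st = walk_traceback(tb, read, ref, n_col, m, best_j, match,
                                 mismatch, wild, nullptr, &ref_start);
  double identity = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
  return List::create(_["score"] = best_score, _["matches"] = st.matches,
                      _["columns"] = st.columns, _["identity"] = identity,
                      _["ref_start"] = best_j > 0 ? ref_start : 0,
                      _["ref_end"] = best_j);
}

// [[Rcpp::export]]
List cpp_align_local(std::string a, std::string b, int match, int mismatch,
                     int gap, std::string wild) {
  int m = a.size(), n = b.size();
  int n_col = n + 1;
  std::vector<int> s((size_t)(m + 1) * n_col, 0);
  std::vector<unsigned char> tb((size_t)(m + 1) * n_col, 0);
  int best_score = 0, best_i = 0, best_j = 0;
  for (int i = 1; i <= m; i++) {
    for (int j = 1; j <= n; j++) {
      int d = s[(size_t)(i - 1) * n_col + (j - 1)] +
              pair_score(a[i - 1], b[j - 1], match, mismatch, wild);
      int u = s[(size_t)(i - 1) * n_col + j] + gap;
      int l = s[(size_t)i * n_col + (j - 1)] + gap;
      int best; unsigned char mv;
      if (d >= u && d >= l) { best = d; mv = 1; }
      else if (u >= l)      { best = u; mv = 2; }
      else                  { best = l; mv = 3; }
      if (best <= 0) { best = 0; mv = 0; }
      s[(size_t)i * n_col + j] = best;
      tb[(size_t)i * n_col + j] = mv;
      if (best > best_score) { best_score = best; best_i = i; best_j = j; }
    }
  }
  int a_start = 0, b_start = 0;
  TraceStats st = {0, 0};
  if (best_score > 0)
    st = walk_traceback(tb, a, b, n_col, best_i, best_j, match, mismatch, wild,
                        &a_start, &b_start);
  double identity = st.columns > 0 ? (double)st.matches / st.columns : 0.0;
  return List::create(_["score"] = best_score, _["matches"] = st.matches,
                      _["columns"] = st.columns, _["identity"] = identity,
                      _["a_start"] = best_score > 0 ? a_start : 0,
                      _["a_end"] = best_i, _["b_start"] = best_score > 0 ? b_start : 0,
                      _["b_end"] = best_j);
}

// All-against-all global identities (used for OTU clustering and its oracle
// tests). Returns a symmetric matrix with unit diagonal.
// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(std::vector<std::string> seqs, int match,
                                  int mismatch, int gap, std::string wild) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; i++) out(i, i) = 1.0;
  for (int i = 0; i < n - 1; i++) {
    for (int j = i + 1; j < n; j++) {
      List r = cpp_align_global(seqs[i], seqs[j], match, mismatch, gap, wild);
      double id = as<double>(r["identity"]);
      out(i, j) = id;
      out(j, i) = id;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batch semi-global: one read against many references; returns per-reference
// identity and score.
// [[Rcpp::export]]
DataFrame cpp_overlap_many(std::string read, std::vector<std::string> refs,
                           int match, int mismatch, int gap, std::string wild) {
  int n = refs.size();
  NumericVector identity(n), score(n);
  for (int i = 0; i < n; i++) {
    List r = cpp_align_overlap(read, refs[i], match, mismatch, gap, wild);
    identity[i] = as<double>(r["identity"]);
    score[i] = as<int>(r["score"]);
  }
  return DataFrame::create(_["identity"] = identity, _["score"] = score);
}
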