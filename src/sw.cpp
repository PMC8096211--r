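#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps and full traceback.
// Scores follow the bwa-mem-like defaults used throughout the package:
// match +1, mismatch -2, gap open -3, gap extend -1 (open cost charged on
// the first gapped base, i.e. a 1-base gap costs gap_open).
//
// Returns 0-based half-open coordinates on query and subject, the number of
// matching columns and the total number of aligned columns (including gaps).

struct SWResult {
  int score, q_start, q_end, s_start, s_end, matches, aligned_len;
};

static SWResult sw_core(const std::string& q, const std::string& s,
                        int match, int mismatch, int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  // DP over three states: M (diag), X (gap in subject: consume query),
  // Y (gap in query: consume subject).
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), H(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), E(n + 1, NEG); // gap in query (horizontal over s)
  std::vector<int> F(n + 1, NEG);                    // gap in subject (vertical over q)
  // traceback: 0 stop, 1 diag, 2 up (query gap? see below), 3 left
  // tb for H: which predecessor produced H[i][j]
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    H[0] = 0; E[0] = NEG;
    int Fi = NEG;
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (move left along subject)
      int e_open = H[j - 1] - gap_open;
      int e_ext = E[j - 1] - gap_extend;
      E[j] = e_open >= e_ext ? e_open : e_ext;
      tbE[(size_t)i * (n + 1) + j] = e_ext > e_open ? 1 : 0;
      // F: gap in subject (move up along query)
      int f_open = Hprev[j] - gap_open;
      int f_ext = F[j] - gap_extend;
      Fi = f_open >= f_ext ? f_open : f_ext;
      tbF[(size_t)i * (n + 1) + j] = f_ext > f_open ? 1 : 0;
      F[j] = Fi;
      char qc = q[i - 1], sc = s[j - 1];
      int sub = (qc == sc && qc != 'N') ? match : mismatch;
      int diag = Hprev[j - 1] + sub;
      int h = diag;
      unsigned char t = 1;
      if (E[j] > h) { h = E[j]; t = 3; }
      if (Fi > h) { h = Fi; t = 2; }
      if (h <= 0) { h = 0; t = 0; }
      H[j] = h;
      tb[(size_t)i * (n + 1) + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, H);
    std::swap(Eprev, E);
  }
  SWResult r; r.score = best;
  r.q_end = bi; r.s_end = bj;
  r.matches = 0; r.aligned_len = 0;
  // traceback
  int i = bi, j = bj;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char t = tb[(size_t)i * (n + 1) + j];
      if (t == 0) break;
      if (t == 1) {
        r.aligned_len++;
        if (q[i - 1] == s[j - 1] && q[i - 1] != 'N') r.matches++;
        --i; --j;
      } else if (t == 2) {
        state = 2;
      } else {
        state = 3;
      }
    } else if (state == 2) { // in F: gap in subject, consume query
      r.aligned_len++;
      unsigned char ext = tbF[(size_t)i * (n + 1) + j];
      --i;
      if (!ext) state = 0;
    } else { // in E: gap in query, consume subject
      r.aligned_len++;
      unsigned char ext = tbE[(size_t)i * (n + 1) + j];
      --j;
      if (!ext) state = 0;
    }
  }
  r.q_start = i; r.s_start = j;
  return r;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match = 1, int mismatch = -2,
                  int gap_open = 3, int gap_extend = 1) {
  SWResult r = sw_core(query, subject, match, mismatch, gap_open, gap_extend);
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end,
    _["matches"] = r.matches, _["aligned_len"] = r.aligned_len);
}

// Paired batch: align query[i] against subject[i] for all i. Used by the
// seeded search, where each query gets a small consensus window.
// [[Rcpp::export(name = ".sw_align_pairs_cpp")]]
IntegerMatrix sw_align_pairs_cpp(CharacterVector queries,
                                 CharacterVector subjects,
                                 int match = 1, int mismatch = -2,
                                 int gap_open = 3, int gap_extend = 1) {
  int n = queries.size();
  if (subjects.size() != n) stop("queries and subjects differ in length");
  IntegerMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(queries[i]);
    std::string s = as<std::string>(subjects[i]);
    SWResult r = sw_core(q, s, match, mismatch, gap_open, gap_extend);
    out(i, 0) = r.score; out(i, 1) = r.q_start; out(i, 2) = r.q_end;
    out(i, 3) = r.s_start; out(i, 4) = r.s_end;
    out(i, 5) = r.matches; out(i, 6) = r.aligned_len;
  }
  colnames(out) = CharacterVector::create("score", "q_start", "q_end",
                                          "s_start", "s_end", "matches",
                                          "aligned_len");
  return out;
}

// Batch variant: align one query against many subjects, return a matrix of
// results (one row per subject). Used by the library-wide search.
// [[Rcpp::export(name = ".sw_align_many_cpp")]]
IntegerMatrix sw_align_many_cpp(std::string query, CharacterVector subjects,
                                int match = 1, int mismatch = -2,
                                int gap_open = 3, int gap_extend = 1) {
  int k = subjects.size();
  IntegerMatrix out(k, 7);
  for (int idx = 0; idx < k; ++idx) {
    std::string s = as<std::string>(subjects[idx]);
    SWResult r = sw_core(query, s, match, mismatch, gap_open, gap_extend);
    out(idx, 0) = r.score; out(idx, 1) = r.q_start; out(idx, 2) = r.q_end;
    out(idx, 3) = r.s_start; out(idx, 4) = r.s_end;
    out(idx, 5) = r.matches; out(idx, 6) = r.aligned_len;
  }
  colnames(out) = CharacterVector::create("score", "q_start", "q_end",
                                          "s_start", "s_end", "matches",
                                          "aligned_len");
  return out;
}
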