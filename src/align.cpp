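#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Unit-cost alignment kernels. Match costs 0, mismatch 1, indel 1.
// 'N' mismatches everything, including another 'N'.

static inline int sub_cost(char a, char b) {
  if (a == 'N' || b == 'N') return 1;
  return a == b ? 0 : 1;
}

// Global (Needleman-Wunsch) alignment with unit costs.
// Traceback preference at equal cost: diagonal, then up (gap in b),
// then left (gap in a) -- deterministic by construction.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("global alignment requires non-empty sequences");
  std::vector<int> D((n + 1) * (m + 1));
  std::vector<unsigned char> P((n + 1) * (m + 1)); // 1 diag, 2 up, 3 left
  const int W = m + 1;
  D[0] = 0;
  for (int i = 1; i <= n; ++i) { D[i * W] = i; P[i * W] = 2; }
  for (int j = 1; j <= m; ++j) { D[j] = j; P[j] = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int cd = D[(i - 1) * W + (j - 1)] + sub_cost(a[i - 1], b[j - 1]);
      int cu = D[(i - 1) * W + j] + 1;
      int cl = D[i * W + (j - 1)] + 1;
      int best = cd; unsigned char p = 1;
      if (cu < best) { best = cu; p = 2; }
      if (cl < best) { best = cl; p = 3; }
      D[i * W + j] = best;
      P[i * W + j] = p;
    }
  }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char p = P[i * W + j];
    if (i > 0 && j > 0 && p == 1) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (p == 2 || j == 0)) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  int matches = 0, gapcols = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == '-' || rb[k] == '-') { ++gapcols; continue; }
    if (ra[k] != 'N' && ra[k] == rb[k]) ++matches;
  }
  return List::create(
    _["cost"] = D[n * W + m],
    _["aln_a"] = ra,
    _["aln_b"] = rb,
    _["aligned_length"] = (int)ra.size(),
    _["matches"] = matches,
    _["gap_columns"] = gapcols);
}

// One start-anchored semi-global pass: align q fully against w[o..],
// the query's first column fixed at window offset o (0-based), trailing
// window bases free. Returns optimal cost only.
static int fit_cost_at(const std::string &q, const std::string &w, int o) {
  const int m = q.size();
  const int L = (int)w.size() - o;
  const int INF = INT_MAX / 4;
  std::vector<int> prev(L + 1), cur(L + 1);
  prev[0] = 0;
  for (int j = 1; j <= L; ++j) prev[j] = INF; // start anchored exactly at o
  int best = INF;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i; // leading deletions (query bases before any window base)
    for (int j = 1; j <= L; ++j) {
      int cd = prev[j - 1] + sub_cost(q[i - 1], w[o + j - 1]);
      int cu = prev[j] + 1;
      int cl = cur[j - 1] + 1;
      int v = cd < cu ? cd : cu;
      if (cl < v) v = cl;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  for (int j = 0; j <= L; ++j) if (prev[j] < best) best = prev[j];
  return best;
}

// Fit (semi-global) alignment of query q inside window w with the
// placement start restricted to [start_min, start_max] (0-based offsets
// from the window start). Query fully consumed; window bases outside the
// placement are free. Ties: smallest offset, then smallest end, then
// diagonal-preferring traceback (substitution over indel, deletion over
// insertion).
// [[Rcpp::export]]
List cpp_fit_align(std::string q, std::string w, int start_min, int start_max) {
  const int m = q.size(), n = w.size();
  if (m == 0) stop("empty query");
  if (n == 0) stop("empty window");
  if (start_min < 0) start_min = 0;
  if (start_max > n - 1) start_max = n - 1;
  if (start_max < start_min) start_max = start_min;
  const int INF = INT_MAX / 4;

  int best_cost = INF, best_o = start_min;
  for (int o = start_min; o <= start_max && o < n; ++o) {
    int c = fit_cost_at(q, w, o);
    if (c < best_cost) { best_cost = c; best_o = o; }
  }

  // Recompute DP with pointers for the winning offset, minimizing
  // (cost, indel count) lexicographically so that substitutions are
  // preferred over equal-cost indel representations.
  const int o = best_o;
  const int L = n - o;
  const int W = L + 1;
  std::vector<int> D((m + 1) * W, INF);
  std::vector<int> G((m + 1) * W, INF); // indel count along the chosen path
  std::vector<unsigned char> P((m + 1) * W, 0);
  D[0] = 0; G[0] = 0;
  for (int i = 1; i <= m; ++i) { D[i * W] = i; G[i * W] = i; P[i * W] = 2; }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= L; ++j) {
      int cd = D[(i - 1) * W + (j - 1)] + sub_cost(q[i - 1], w[o + j - 1]);
      int gd = G[(i - 1) * W + (j - 1)];
      int cu = D[(i - 1) * W + j] + 1, gu = G[(i - 1) * W + j] + 1;
      int cl = D[i * W + (j - 1)] + 1, gl = G[i * W + (j - 1)] + 1;
      int bcst = cd, bg = gd; unsigned char p = 1;
      if (cu < bcst || (cu == bcst && gu < bg)) { bcst = cu; bg = gu; p = 2; }
      if (cl < bcst || (cl == bcst && gl < bg)) { bcst = cl; bg = gl; p = 3; }
      D[i * W + j] = bcst;
      G[i * W + j] = bg;
      P[i * W + j] = p;
    }
  }
  // end column: min cost, then fewest indels, then smallest j
  int jend = 0, bc = INF, bgend = INF;
  for (int j = 0; j <= L; ++j) {
    int c = D[m * W + j], g = G[m * W + j];
    if (c < bc || (c == bc && g < bgend)) { bc = c; bgend = g; jend = j; }
  }
  std::string rq, rw;
  int i = m, j = jend;
  while (i > 0 || j > 0) {
    unsigned char p = P[i * W + j];
    if (i > 0 && j > 0 && p == 1) {
      rq.push_back(q[i - 1]); rw.push_back(w[o + j - 1]); --i; --j;
    } else if (i > 0 && (p == 2 || j == 0)) {
      rq.push_back(q[i - 1]); rw.push_back('-'); --i;
    } else {
      rq.push_back('-'); rw.push_back(w[o + j - 1]); --j;
    }
  }
  std::reverse(rq.begin(), rq.end());
  std::reverse(rw.begin(), rw.end());
  return List::create(
    _["cost"] = bc,
    _["offset"] = o,
    _["end_offset"] = o + jend,
    _["ref_aln"] = rq,
    _["obs_aln"] = rw);
}
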