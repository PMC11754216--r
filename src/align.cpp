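#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// mode 0: global (Needleman-Wunsch); both sequences end to end.
// mode 1: fit; end gaps on the reference (b) are free, so the full query (a)
//         is aligned against the best-scoring substring of the reference.
// mode 2: local (Smith-Waterman); best-scoring block of both sequences.
// query_free (mode 1 only) additionally makes end gaps on the query free
// (overlap-style), for queries truncated relative to the reference.
//
// A gap of length L costs gap_open + (L - 1) * gap_extend.
// 'N' never scores as a match.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_affine")]]
List align_affine(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend,
                  int mode, bool query_free) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  const bool ref_free = (mode == 1);
  const bool local = (mode == 2);
  // layers: M diag, X gap-in-b (consumes a), Y gap-in-a (consumes b)
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: which layer the predecessor cell is in (0=M, 1=X, 2=Y)
  std::vector<signed char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);

  M[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (ref_free || local) M[j] = 0.0;   // start anywhere in the reference
    else { Y[j] = gap_open + (j - 1) * gap_extend; tY[j] = 2; }
  }
  for (int i = 1; i <= n; ++i) {
    if (query_free || local) M[i * W] = 0.0;  // start anywhere in the query
    else { X[i * W] = gap_open + (i - 1) * gap_extend; tX[i * W] = 1; }
  }

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[j - 1];
      const double s =
          (ai == bj && ai != 'N' && bj != 'N') ? match : mismatch;
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double best = M[d]; signed char from = 0;
      if (X[d] > best) { best = X[d]; from = 1; }
      if (Y[d] > best) { best = Y[d]; from = 2; }
      if (local && best < 0.0) { best = 0.0; from = 3; }  // fresh start
      M[c] = best + s; tM[c] = from;

      best = M[u] + gap_open; from = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; from = 1; }
      if (Y[u] + gap_open > best) { best = Y[u] + gap_open; from = 2; }
      X[c] = best; tX[c] = from;

      best = M[l] + gap_open; from = 0;
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; from = 2; }
      if (X[l] + gap_open > best) { best = X[l] + gap_open; from = 1; }
      Y[c] = best; tY[c] = from;
    }
  }

  // choose end cell (ties: earliest considered, i.e. smallest j then i)
  int ei = n, ej = m; signed char elayer = 0;
  double bestScore = NEG_INF;
  auto consider = [&](int i, int j) {
    const int c = i * W + j;
    double v = M[c]; signed char l = 0;
    if (X[c] > v) { v = X[c]; l = 1; }
    if (Y[c] > v) { v = Y[c]; l = 2; }
    if (v > bestScore) { bestScore = v; ei = i; ej = j; elayer = l; }
  };
  if (mode == 0) {
    consider(n, m);
  } else if (mode == 2) {
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j) consider(i, j);
  } else {
    for (int j = 0; j <= m; ++j) consider(n, j);
    if (query_free)
      for (int i = 0; i < n; ++i) consider(i, m);
  }

  // traceback; free end regions are skipped (reported via start/end coords)
  std::string ra, rb;
  int i = ei, j = ej; signed char layer = elayer;
  while (true) {
    if (i == 0 && j == 0) break;
    if (i == 0 && (ref_free || local)) break;
    if (j == 0 && (query_free || local)) break;
    if (i == 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue; }
    const int c = i * W + j;
    if (layer == 0) {
      signed char f = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
      if (f == 3) break;  // local fresh start
      layer = f;
    } else if (layer == 1) {
      signed char f = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-'); --i; layer = f;
    } else {
      signed char f = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]); --j; layer = f;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(
      _["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = bestScore,
      _["a_start"] = i + 1, _["a_end"] = ei,
      _["b_start"] = j + 1, _["b_end"] = ej);
}
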