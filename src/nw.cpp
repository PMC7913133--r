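#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Three-state affine-gap global alignment (Needleman-Wunsch / Gotoh).
// States: M (ai aligned to bj), IX (gap in b, consuming a, the "up" move),
// IY (gap in a, consuming b, the "left" move). A gap of length L costs
// gap_open + L * gap_extend, i.e. the first gap column already pays one
// extension (EMBOSS needle convention). With penalize_end_gaps = false
// (needle default) leading/trailing gaps are free: leading gaps via the
// border initialization, trailing gaps by taking the optimum over the last
// row and column and padding the remainder.
//
// Determinism: every argmax prefers M over IX over IY, and the ends-free
// endpoint scan prefers the bottom-right cell, then the last column bottom
// to top, then the last row right to left, replacing only on strict
// improvement. Together with the state preference this realizes the
// documented diagonal > up > left traceback tie-break.

static const double NEG = -1e30;

struct Cell { double m, ix, iy; };

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector ai, IntegerVector bi, NumericMatrix smat,
                  double gap_open, double gap_extend, bool end_gaps) {
  const int n = ai.size(), m = bi.size();
  const double open = gap_open + gap_extend, ext = gap_extend;

  std::vector<Cell> S((n + 1) * (m + 1));
  // Traceback pointers: predecessor state (0=M,1=IX,2=IY) for each state.
  std::vector<unsigned char> pm(S.size()), px(S.size()), py(S.size());
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  S[at(0, 0)] = {0.0, NEG, NEG};
  for (int i = 1; i <= n; ++i) {
    S[at(i, 0)] = {NEG, end_gaps ? -(open + (i - 1) * ext) : 0.0, NEG};
    px[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    S[at(0, j)] = {NEG, NEG, end_gaps ? -(open + (j - 1) * ext) : 0.0};
    py[at(0, j)] = 2;
  }

  auto best3 = [](double vm, double vx, double vy, unsigned char &ptr) {
    double b = vm; ptr = 0;
    if (vx > b) { b = vx; ptr = 1; }
    if (vy > b) { b = vy; ptr = 2; }
    return b;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const Cell &d = S[at(i - 1, j - 1)];
      const Cell &u = S[at(i - 1, j)];
      const Cell &l = S[at(i, j - 1)];
      Cell &c = S[at(i, j)];
      unsigned char p;
      double s = smat(ai[i - 1], bi[j - 1]);
      c.m = s + best3(d.m, d.ix, d.iy, p); pm[at(i, j)] = p;
      c.ix = best3(u.m - open, u.ix - ext, u.iy - open, p); px[at(i, j)] = p;
      c.iy = best3(l.m - open, l.iy - ext, l.ix - open, p);
      // best3 orders (vm, vx, vy); for IY the middle argument was iy:
      py[at(i, j)] = (p == 1) ? 2 : (p == 2 ? 1 : 0);
    }
  }

  // Endpoint selection.
  int ei = n, ej = m; unsigned char estate;
  double score;
  {
    const Cell &c = S[at(n, m)];
    unsigned char p;
    score = best3(c.m, c.ix, c.iy, p);
    estate = p;
  }
  if (!end_gaps) {
    for (int i = n - 1; i >= 0; --i) {
      const Cell &c = S[at(i, m)];
      unsigned char p;
      double v = best3(c.m, c.ix, c.iy, p);
      if (v > score) { score = v; ei = i; ej = m; estate = p; }
    }
    for (int j = m - 1; j >= 0; --j) {
      const Cell &c = S[at(n, j)];
      unsigned char p;
      double v = best3(c.m, c.ix, c.iy, p);
      if (v > score) { score = v; ei = n; ej = j; estate = p; }
    }
  }

  std::string ra, rb;
  // Trailing free end gaps for the part not covered by the chosen endpoint.
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(char('0' + 2)); }
  for (int i = n; i > ei; --i) { ra.push_back(char('0' + 1)); rb.push_back('-'); }

  int i = ei, j = ej; unsigned char st = estate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (i == 0 || j == 0) break;
      unsigned char p = pm[at(i, j)];
      ra.push_back(char('0' + 1)); rb.push_back(char('0' + 2));
      --i; --j; st = p;
    } else if (st == 1) {
      unsigned char p = px[at(i, j)];
      ra.push_back(char('0' + 1)); rb.push_back('-');
      --i; st = p;
      if (i == 0 && j == 0) break;
      if (j == 0 && !end_gaps) { // free leading gap region
        while (i > 0) { ra.push_back(char('0' + 1)); rb.push_back('-'); --i; }
        break;
      }
    } else {
      unsigned char p = py[at(i, j)];
      ra.push_back('-'); rb.push_back(char('0' + 2));
      --j; st = p;
      if (i == 0 && j == 0) break;
      if (i == 0 && !end_gaps) {
        while (j > 0) { ra.push_back('-'); rb.push_back(char('0' + 2)); --j; }
        break;
      }
    }
  }
  // Any remaining border prefix (end_gaps = true walks the border states
  // through the same pointer logic; guard for completeness).
  while (i > 0) { ra.push_back(char('0' + 1)); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(char('0' + 2)); --j; }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // Replace placeholders with running residue indices (0-based, for R to
  // translate back into characters).
  IntegerVector ia(ra.size()), ib(rb.size());
  int ca = 0, cb = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    ia[k] = (ra[k] == '-') ? -1 : ca++;
    ib[k] = (rb[k] == '-') ? -1 : cb++;
  }
  if (ca != n || cb != m) stop("internal traceback error");

  return List::create(_["score"] = score, _["ia"] = ia, _["ib"] = ib);
}
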