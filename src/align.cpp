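#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e30;

// Local affine-gap alignment (Gotoh three-state recurrences, score floored
// at zero). a and b are 1-based codes into submat. A gap of length k costs
// gap_open + (k-1) * gap_extend. The single best hit is returned; ties on
// the optimal score are broken by the smallest end coordinate in a, then in
// b (the forward scan keeps the first strictly better cell). Returned
// coordinates are 1-based inclusive; a score of 0 means an empty hit.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);

  NumericMatrix M(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  // pointer codes: 0 = fresh start (M only), 1 = from M, 2 = from E, 3 = from F
  IntegerMatrix PM(m + 1, n + 1), PE(m + 1, n + 1), PF(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { M(0, j) = 0.0; E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { M(i, 0) = 0.0; E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double s = submat(a[i - 1] - 1, b[j - 1] - 1);
      // M: a_i aligned to b_j
      double dM = M(i - 1, j - 1), dE = E(i - 1, j - 1), dF = F(i - 1, j - 1);
      double diag = dM; int dp = 1;
      if (dE > diag) { diag = dE; dp = 2; }
      if (dF > diag) { diag = dF; dp = 3; }
      if (diag <= 0.0) { diag = 0.0; dp = 0; }
      double mv = diag + s;
      if (mv < 0.0) mv = 0.0;
      M(i, j) = mv;
      PM(i, j) = dp;
      // E: gap in a, consuming b_j
      double e1 = M(i, j - 1) - gap_open;
      double e2 = E(i, j - 1) - gap_extend;
      double e3 = F(i, j - 1) - gap_open;
      double ev = e1; int ep = 1;
      if (e2 > ev) { ev = e2; ep = 2; }
      if (e3 > ev) { ev = e3; ep = 3; }
      E(i, j) = ev; PE(i, j) = ep;
      // F: gap in b, consuming a_i
      double f1 = M(i - 1, j) - gap_open;
      double f2 = E(i - 1, j) - gap_open;
      double f3 = F(i - 1, j) - gap_extend;
      double fv = f1; int fp = 1;
      if (f2 > fv) { fv = f2; fp = 2; }
      if (f3 > fv) { fv = f3; fp = 3; }
      F(i, j) = fv; PF(i, j) = fp;
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);

  // traceback from the best cell (always in state M)
  int i = bi, j = bj, state = 1, astart = bi, bstart = bj;
  for (;;) {
    if (state == 1) {
      astart = i; bstart = j;
      int p = PM(i, j);
      if (p == 0) break;
      state = p; --i; --j;
    } else if (state == 2) {
      state = PE(i, j); --j;
    } else {
      state = PF(i, j); --i;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = astart, _["a_end"] = bi,
                      _["b_start"] = bstart, _["b_end"] = bj);
}

// Global profile-profile alignment with affine gaps.
// cs(i,j): expected substitution score of p column i against q column j.
// gp, gq: per-column gap fractions; a gap placed against a column is charged
// penalty * (1 - gap fraction of the consumed column).
// terminal_free: 0 = none, 1 = q_side (gaps in q at either end are free,
// i.e. p columns are consumed for free before the first / after the last q
// column), 2 = both sides.
// Tie-breaking, applied identically in the forward pass and at the final
// cell: prefer match (M), then gap-in-q (X, consumes a p column), then
// gap-in-p (Y, consumes a q column).
// Returns the optimal score and the column trace as two integer vectors
// (1-based column index, 0 = gap).
// [[Rcpp::export]]
List profile_dp_cpp(NumericMatrix cs, NumericVector gp, NumericVector gq,
                    double gap_open, double gap_extend, int terminal_free) {
  const int L = cs.nrow(), R = cs.ncol();
  const bool freeq = terminal_free >= 1;
  const bool freep = terminal_free == 2;
  NumericMatrix M(L + 1, R + 1), X(L + 1, R + 1), Y(L + 1, R + 1);
  IntegerMatrix PM(L + 1, R + 1), PX(L + 1, R + 1), PY(L + 1, R + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= L; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    const double w = 1.0 - gp[i - 1];
    const double c = freeq ? 0.0 : ((i == 1 ? gap_open : gap_extend) * w);
    X(i, 0) = (i == 1 ? M(0, 0) : X(i - 1, 0)) - c;
    PX(i, 0) = (i == 1 ? 1 : 2);
  }
  for (int j = 1; j <= R; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    const double w = 1.0 - gq[j - 1];
    const double c = freep ? 0.0 : ((j == 1 ? gap_open : gap_extend) * w);
    Y(0, j) = (j == 1 ? M(0, 0) : Y(0, j - 1)) - c;
    PY(0, j) = (j == 1 ? 1 : 3);
  }

  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= R; ++j) {
      // M
      double c0 = M(i - 1, j - 1), c1 = X(i - 1, j - 1), c2 = Y(i - 1, j - 1);
      double bv = c0; int bp = 1;
      if (c1 > bv) { bv = c1; bp = 2; }
      if (c2 > bv) { bv = c2; bp = 3; }
      M(i, j) = bv + cs(i - 1, j - 1);
      PM(i, j) = bp;
      // X: consume p column i against a gap in q
      {
        const double w = 1.0 - gp[i - 1];
        const bool f = freeq && j == R;
        const double oc = f ? 0.0 : gap_open * w;
        const double ec = f ? 0.0 : gap_extend * w;
        double x0 = M(i - 1, j) - oc, x1 = X(i - 1, j) - ec, x2 = Y(i - 1, j) - oc;
        double xv = x0; int xp = 1;
        if (x1 > xv) { xv = x1; xp = 2; }
        if (x2 > xv) { xv = x2; xp = 3; }
        X(i, j) = xv; PX(i, j) = xp;
      }
      // Y: consume q column j against a gap in p
      {
        const double w = 1.0 - gq[j - 1];
        const bool f = freep && i == L;
        const double oc = f ? 0.0 : gap_open * w;
        const double ec = f ? 0.0 : gap_extend * w;
        double y0 = M(i, j - 1) - oc, y1 = X(i, j - 1) - oc, y2 = Y(i, j - 1) - ec;
        double yv = y0; int yp = 1;
        if (y1 > yv) { yv = y1; yp = 2; }
        if (y2 > yv) { yv = y2; yp = 3; }
        Y(i, j) = yv; PY(i, j) = yp;
      }
    }
  }

  double fin = M(L, R); int state = 1;
  if (X(L, R) > fin) { fin = X(L, R); state = 2; }
  if (Y(L, R) > fin) { fin = Y(L, R); state = 3; }

  std::vector<int> left, right;
  left.reserve(L + R); right.reserve(L + R);
  int i = L, j = R;
  while (i > 0 || j > 0) {
    if (state == 1) {
      left.push_back(i); right.push_back(j);
      state = PM(i, j); --i; --j;
    } else if (state == 2) {
      left.push_back(i); right.push_back(0);
      state = PX(i, j); --i;
    } else {
      left.push_back(0); right.push_back(j);
      state = PY(i, j); --j;
    }
  }
  std::reverse(left.begin(), left.end());
  std::reverse(right.begin(), right.end());
  return List::create(_["score"] = fin,
                      _["left"] = wrap(left), _["right"] = wrap(right));
}
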