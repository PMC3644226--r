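#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global pairwise alignment (Gotoh), maximising. A gap of length
// L costs open + ext * L (both passed as positive costs). The DP is
// restricted to a diagonal band of half-width `band` around the main
// diagonal (pass band >= max(la, lb) for the full matrix). Tie order in the
// traceback: match/mismatch > gap-in-b > gap-in-a, matching the R-level
// documentation of align_center_star().

static inline int code_of(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return 4;
  }
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double open, double ext, int band, bool score_only) {
  const int la = (int)a.size(), lb = (int)b.size();
  const double NEG = -1e18;
  double SUB[5][5];
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j)
      SUB[i][j] = (i == 4 || j == 4) ? 0.0 : (i == j ? match : mismatch);
  std::vector<int> ac(la), bc(lb);
  for (int i = 0; i < la; ++i) ac[i] = code_of(a[i]);
  for (int j = 0; j < lb; ++j) bc[j] = code_of(b[j]);

  const int d = lb - la;
  const int dmin = d < 0 ? d : 0, dmax = d > 0 ? d : 0;
  const int W = dmax - dmin + 2 * band + 1;
  auto lo_of = [&](int i) { int v = i + dmin - band; return v > 0 ? v : 0; };
  auto hi_of = [&](int i) { int v = i + dmax + band; return v < lb ? v : lb; };

  std::vector<double> M((size_t)(la + 1) * W, NEG),
                      X((size_t)(la + 1) * W, NEG),
                      Y((size_t)(la + 1) * W, NEG);
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - lo_of(i)); };
  auto getM = [&](int i, int j) {
    return (j < lo_of(i) || j > hi_of(i)) ? NEG : M[idx(i, j)];
  };
  auto getX = [&](int i, int j) {
    return (j < lo_of(i) || j > hi_of(i)) ? NEG : X[idx(i, j)];
  };
  auto getY = [&](int i, int j) {
    return (j < lo_of(i) || j > hi_of(i)) ? NEG : Y[idx(i, j)];
  };

  M[idx(0, 0)] = 0.0;
  for (int j = std::max(1, lo_of(0)); j <= hi_of(0); ++j)
    Y[idx(0, j)] = -open - ext * j;
  const double oe = open + ext;
  for (int i = 1; i <= la; ++i) {
    const int lo = lo_of(i), hi = hi_of(i);
    const int plo = lo_of(i - 1), phi = hi_of(i - 1);
    const double *Mp = &M[(size_t)(i - 1) * W];
    const double *Xp = &X[(size_t)(i - 1) * W];
    const double *Yp = &Y[(size_t)(i - 1) * W];
    double *Mc = &M[(size_t)i * W] - lo;   // index by absolute j
    double *Xc = &X[(size_t)i * W] - lo;
    double *Yc = &Y[(size_t)i * W] - lo;
    const double *subrow = SUB[ac[i - 1]];
    // branch-free body: j-1 and j both within the previous row's window
    const int body_lo = std::max(lo + 1, std::max(plo + 1, 1));
    const int body_hi = std::min(hi, phi);
    auto cell = [&](int j) {
      if (j == 0) { Xc[0] = -open - ext * i; return; }
      double pM1 = getM(i - 1, j - 1), pX1 = getX(i - 1, j - 1),
             pY1 = getY(i - 1, j - 1);
      double best = pM1 > pX1 ? pM1 : pX1;
      if (pY1 > best) best = pY1;
      Mc[j] = subrow[bc[j - 1]] + best;
      double pM0 = getM(i - 1, j), pX0 = getX(i - 1, j), pY0 = getY(i - 1, j);
      double xo = pM0 > pY0 ? pM0 : pY0;
      double xv = xo - oe, xe2 = pX0 - ext;
      Xc[j] = xv > xe2 ? xv : xe2;
      double mL = (j - 1 >= lo) ? Mc[j - 1] : getM(i, j - 1);
      double xL = (j - 1 >= lo) ? Xc[j - 1] : getX(i, j - 1);
      double yL = (j - 1 >= lo) ? Yc[j - 1] : getY(i, j - 1);
      double yo = mL > xL ? mL : xL;
      double yv = yo - oe, ye2 = yL - ext;
      Yc[j] = yv > ye2 ? yv : ye2;
    };
    for (int j = lo; j < std::min(body_lo, hi + 1); ++j) cell(j);
    for (int j = body_lo; j <= body_hi; ++j) {
      const int jp = j - plo;                 // index into previous row
      double pM1 = Mp[jp - 1], pX1 = Xp[jp - 1], pY1 = Yp[jp - 1];
      double best = pM1 > pX1 ? pM1 : pX1;
      if (pY1 > best) best = pY1;
      Mc[j] = subrow[bc[j - 1]] + best;
      double pM0 = Mp[jp], pX0 = Xp[jp], pY0 = Yp[jp];
      double xo = pM0 > pY0 ? pM0 : pY0;
      double xv = xo - oe, xe2 = pX0 - ext;
      Xc[j] = xv > xe2 ? xv : xe2;
      double mL = Mc[j - 1], xL = Xc[j - 1], yL = Yc[j - 1];
      double yo = mL > xL ? mL : xL;
      double yv = yo - oe, ye2 = yL - ext;
      Yc[j] = yv > ye2 ? yv : ye2;
    }
    for (int j = std::max(body_hi + 1, body_lo); j <= hi; ++j) cell(j);
  }

  double fm = getM(la, lb), fx = getX(la, lb), fy = getY(la, lb);
  int state = 1;
  double score = fm;
  if (fx > score) { score = fx; state = 2; }
  if (fy > score) { score = fy; state = 3; }
  if (score_only)
    return List::create(_["score"] = score);

  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  int i = la, j = lb;
  const double tol = 1e-6;
  while (i > 0 || j > 0) {
    if (state == 1) {
      double s = SUB[ac[i - 1]][bc[j - 1]];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double val = getM(i, j) - s;
      --i; --j;
      if (std::abs(getM(i, j) - val) < tol) state = 1;
      else if (std::abs(getX(i, j) - val) < tol) state = 2;
      else if (std::abs(getY(i, j) - val) < tol) state = 3;
      else stop("alignment traceback failed");
    } else if (state == 2) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      double val = getX(i, j);
      --i;
      if (std::abs(getM(i, j) - open - ext - val) < tol) state = 1;
      else if (std::abs(getX(i, j) - ext - val) < tol) state = 2;
      else if (std::abs(getY(i, j) - open - ext - val) < tol) state = 3;
      else stop("alignment traceback failed");
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double val = getY(i, j);
      --j;
      if (std::abs(getM(i, j) - open - ext - val) < tol) state = 1;
      else if (std::abs(getX(i, j) - open - ext - val) < tol) state = 2;
      else if (std::abs(getY(i, j) - ext - val) < tol) state = 3;
      else stop("alignment traceback failed");
    }
    if (i == 0 && j == 0) break;
    if (i == 0) state = 3;
    else if (j == 0) state = 2;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a_aln"] = ra, _["b_aln"] = rb, _["score"] = score);
}
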