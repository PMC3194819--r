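#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Per-window texture kernels. Windows are square (side `win`, odd), centred
// on 1-based (row, col) pixel coordinates; callers guarantee the window fits
// inside the image. Gray-level inputs for co-occurrence / run-length are
// integer-quantized images (0-based levels).

static const int ANG_DR[4] = {0, -1, -1, -1};  // 0, 45, 90, 135 degrees
static const int ANG_DC[4] = {1,  1,  0, -1};

// gray-level co-occurrence features for one window, one (distance, angle):
// symmetric normalized matrix; energy, contrast, correlation, homogeneity,
// entropy, dissimilarity
static void glcm_one(const IntegerMatrix &img, int r0, int c0, int win,
                     int dist, int ang, double *out) {
  int half = win / 2;
  int dr = ANG_DR[ang] * dist, dc = ANG_DC[ang] * dist;
  std::vector<int> codes;
  codes.reserve(2 * win * win);
  double contrast = 0, dissim = 0, homog = 0;
  int L = 0;  // max level+1 for pair coding
  for (int a = -half; a <= half; ++a)
    for (int b = -half; b <= half; ++b) {
      int g = img(r0 + a, c0 + b);
      if (g + 1 > L) L = g + 1;
    }
  int n = 0;
  for (int a = -half; a <= half; ++a) {
    for (int b = -half; b <= half; ++b) {
      int a2 = a + dr, b2 = b + dc;
      if (a2 < -half || a2 > half || b2 < -half || b2 > half) continue;
      int i = img(r0 + a, c0 + b);
      int j = img(r0 + a2, c0 + b2);
      // symmetric: count both (i,j) and (j,i)
      codes.push_back(i * L + j);
      codes.push_back(j * L + i);
      double d = std::abs(i - j);
      contrast += 2.0 * d * d;
      dissim += 2.0 * d;
      homog += 2.0 / (1.0 + d * d);
      n += 2;
    }
  }
  if (n == 0) {
    for (int k = 0; k < 6; ++k) out[k] = NA_REAL;
    return;
  }
  double N = n;
  contrast /= N; dissim /= N; homog /= N;
  // marginal moments over all matrix entries (one per code)
  double si = 0, si2 = 0, sij = 0;
  for (size_t k = 0; k < codes.size(); ++k) {
    int i = codes[k] / L, j = codes[k] % L;
    si += i; si2 += (double)i * i; sij += (double)i * j;
  }
  si /= N; si2 /= N; sij /= N;
  double var_i = si2 - si * si;
  double corr = (var_i > 1e-12) ? (sij - si * si) / var_i : 0.0;
  std::sort(codes.begin(), codes.end());
  double energy = 0, entropy = 0;
  size_t k = 0;
  while (k < codes.size()) {
    size_t k2 = k;
    while (k2 < codes.size() && codes[k2] == codes[k]) ++k2;
    double p = (double)(k2 - k) / N;
    energy += p * p;
    entropy -= p * std::log2(p);
    k = k2;
  }
  out[0] = energy; out[1] = contrast; out[2] = corr;
  out[3] = homog; out[4] = entropy; out[5] = dissim;
}

// [[Rcpp::export]]
NumericMatrix cpp_glcm_stack(IntegerMatrix img, IntegerVector rows,
                             IntegerVector cols, int win,
                             IntegerVector distances) {
  int np = rows.size(), nd = distances.size();
  NumericMatrix out(np, nd * 4 * 6);
  for (int p = 0; p < np; ++p) {
    int r0 = rows[p] - 1, c0 = cols[p] - 1;
    int col = 0;
    for (int d = 0; d < nd; ++d)
      for (int a = 0; a < 4; ++a) {
        double f[6];
        glcm_one(img, r0, c0, win, distances[d], a, f);
        for (int k = 0; k < 6; ++k) out(p, col + k) = f[k];
        col += 6;
      }
  }
  return out;
}

// run-length features for one window, one direction: short-run emphasis,
// long-run emphasis, gray-level non-uniformity, run-length non-uniformity,
// run percentage
static void rlm_one(const IntegerMatrix &img, int r0, int c0, int win,
                    int ang, int levels, double *out) {
  int half = win / 2;
  std::vector<double> gl_count(levels, 0.0);
  std::vector<double> len_count(win + 1, 0.0);
  double nr = 0, sre = 0, lre = 0;
  int dr = ANG_DR[ang], dc = ANG_DC[ang];
  // enumerate line start points: cells with no in-window predecessor
  for (int a = -half; a <= half; ++a) {
    for (int b = -half; b <= half; ++b) {
      int pa = a - dr, pb = b - dc;
      bool has_pred = (pa >= -half && pa <= half && pb >= -half && pb <= half);
      if (has_pred) continue;
      // walk the line
      int ca = a, cb = b;
      int cur = -1, len = 0;
      while (ca >= -half && ca <= half && cb >= -half && cb <= half) {
        int g = img(r0 + ca, c0 + cb);
        if (g == cur) {
          ++len;
        } else {
          if (len > 0) {
            nr += 1; sre += 1.0 / ((double)len * len); lre += (double)len * len;
            gl_count[cur] += 1; len_count[len] += 1;
          }
          cur = g; len = 1;
        }
        ca += dr; cb += dc;
      }
      if (len > 0) {
        nr += 1; sre += 1.0 / ((double)len * len); lre += (double)len * len;
        gl_count[cur] += 1; len_count[len] += 1;
      }
    }
  }
  double gln = 0, rln = 0;
  for (int g = 0; g < levels; ++g) gln += gl_count[g] * gl_count[g];
  for (int l = 0; l <= win; ++l) rln += len_count[l] * len_count[l];
  double npix = (double)win * win;
  out[0] = sre / nr; out[1] = lre / nr;
  out[2] = gln / nr; out[3] = rln / nr; out[4] = nr / npix;
}

// [[Rcpp::export]]
NumericMatrix cpp_rlm_stack(IntegerMatrix img, IntegerVector rows,
                            IntegerVector cols, int win, int levels) {
  int np = rows.size();
  NumericMatrix out(np, 4 * 5);
  for (int p = 0; p < np; ++p) {
    int r0 = rows[p] - 1, c0 = cols[p] - 1;
    for (int a = 0; a < 4; ++a) {
      double f[5];
      rlm_one(img, r0, c0, win, a, levels, f);
      for (int k = 0; k < 5; ++k) out(p, a * 5 + k) = f[k];
    }
  }
  return out;
}

// differential box counting: per window, per grid size s, count boxes needed
// to cover the intensity surface; intensities are rescaled to [0, levels-1]
// relative to the window's own range (hence offset-invariant)
// [[Rcpp::export]]
NumericMatrix cpp_dbc_counts(NumericMatrix img, IntegerVector rows,
                             IntegerVector cols, int win,
                             IntegerVector sizes, int levels) {
  int np = rows.size(), ns = sizes.size();
  int half = win / 2;
  NumericMatrix out(np, ns);
  for (int p = 0; p < np; ++p) {
    int r0 = rows[p] - 1, c0 = cols[p] - 1;
    double mn = R_PosInf, mx = R_NegInf;
    for (int a = -half; a <= half; ++a)
      for (int b = -half; b <= half; ++b) {
        double v = img(r0 + a, c0 + b);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
    double range = mx - mn;
    for (int s = 0; s < ns; ++s) {
      int sz = sizes[s];
      int g = win / sz;                   // full blocks per side
      double h = (double)levels * sz / win;  // box height at this scale
      double N = 0;
      for (int bi = 0; bi < g; ++bi) {
        for (int bj = 0; bj < g; ++bj) {
          double bmn = R_PosInf, bmx = R_NegInf;
          for (int a = 0; a < sz; ++a)
            for (int b = 0; b < sz; ++b) {
              double v = img(r0 - half + bi * sz + a, c0 - half + bj * sz + b);
              if (v < bmn) bmn = v;
              if (v > bmx) bmx = v;
            }
          double zmin = 0, zmax = 0;
          if (range > 0) {
            zmin = (bmn - mn) / range * (levels - 1);
            zmax = (bmx - mn) / range * (levels - 1);
          }
          N += std::floor(zmax / h) - std::floor(zmin / h) + 1.0;
        }
      }
      out(p, s) = N;
    }
  }
  return out;
}

// Gauss-Markov random field parameters by ridge-stabilized least squares:
// each interior pixel regressed on its symmetric neighbour sums
// (horizontal, vertical, and the two diagonals for order 2) plus an
// intercept; returns the neighbour coefficients and the residual variance
// [[Rcpp::export]]
NumericMatrix cpp_mrf_stack(NumericMatrix img, IntegerVector rows,
                            IntegerVector cols, int win, int order) {
  int np = rows.size();
  int nnb = (order >= 2) ? 4 : 2;
  int dim = nnb + 1;  // + intercept
  NumericMatrix out(np, nnb + 1);  // thetas + sigma2
  int half = win / 2;
  std::vector<double> XtX(dim * dim), Xty(dim), x(dim);
  for (int p = 0; p < np; ++p) {
    int r0 = rows[p] - 1, c0 = cols[p] - 1;
    // constant window: regression undefined; report zero parameters
    bool constant = true;
    double v0 = img(r0 - half, c0 - half);
    for (int a = -half; a <= half && constant; ++a)
      for (int b = -half; b <= half; ++b)
        if (img(r0 + a, c0 + b) != v0) { constant = false; break; }
    if (constant) {
      for (int k = 0; k <= nnb; ++k) out(p, k) = 0.0;
      continue;
    }
    std::fill(XtX.begin(), XtX.end(), 0.0);
    std::fill(Xty.begin(), Xty.end(), 0.0);
    double yty = 0;
    int nobs = 0;
    for (int a = -half + 1; a <= half - 1; ++a) {
      for (int b = -half + 1; b <= half - 1; ++b) {
        int r = r0 + a, c = c0 + b;
        double y = img(r, c);
        x[0] = 1.0;
        x[1] = img(r, c - 1) + img(r, c + 1);          // horizontal
        x[2] = img(r - 1, c) + img(r + 1, c);          // vertical
        if (order >= 2) {
          x[3] = img(r - 1, c - 1) + img(r + 1, c + 1);  // main diagonal
          x[4] = img(r - 1, c + 1) + img(r + 1, c - 1);  // anti-diagonal
        }
        for (int i = 0; i < dim; ++i) {
          Xty[i] += x[i] * y;
          for (int j = i; j < dim; ++j) XtX[i * dim + j] += x[i] * x[j];
        }
        yty += y * y;
        ++nobs;
      }
    }
    for (int i = 0; i < dim; ++i)
      for (int j = 0; j < i; ++j) XtX[i * dim + j] = XtX[j * dim + i];
    // ridge for near-singular designs (e.g. constant or perfectly striped
    // windows); keeps the solution defined and deterministic
    double tr = 0;
    for (int i = 0; i < dim; ++i) tr += XtX[i * dim + i];
    double eps = 1e-9 * (tr / dim + 1.0);
    std::vector<double> A(XtX);
    for (int i = 0; i < dim; ++i) A[i * dim + i] += eps;
    std::vector<double> bvec(Xty);
    // gaussian elimination with partial pivoting
    std::vector<int> piv(dim);
    for (int i = 0; i < dim; ++i) piv[i] = i;
    for (int col = 0; col < dim; ++col) {
      int best = col;
      for (int r2 = col + 1; r2 < dim; ++r2)
        if (std::fabs(A[r2 * dim + col]) > std::fabs(A[best * dim + col]))
          best = r2;
      if (best != col) {
        for (int j = 0; j < dim; ++j) std::swap(A[col * dim + j], A[best * dim + j]);
        std::swap(bvec[col], bvec[best]);
      }
      double pivv = A[col * dim + col];
      for (int r2 = col + 1; r2 < dim; ++r2) {
        double f = A[r2 * dim + col] / pivv;
        for (int j = col; j < dim; ++j) A[r2 * dim + j] -= f * A[col * dim + j];
        bvec[r2] -= f * bvec[col];
      }
    }
    std::vector<double> theta(dim);
    for (int i = dim - 1; i >= 0; --i) {
      double v = bvec[i];
      for (int j = i + 1; j < dim; ++j) v -= A[i * dim + j] * theta[j];
      theta[i] = v / A[i * dim + i];
    }
    // residual variance
    double rss = yty;
    for (int i = 0; i < dim; ++i) {
      rss -= 2.0 * theta[i] * Xty[i];
      for (int j = 0; j < dim; ++j) rss += theta[i] * theta[j] * XtX[i * dim + j];
    }
    if (rss < 0) rss = 0;
    for (int k = 0; k < nnb; ++k) out(p, k) = theta[k + 1];
    out(p, nnb) = rss / std::max(nobs, 1);
  }
  return out;
}
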