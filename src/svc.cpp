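// Linear support vector classification (C-SVC, linear kernel) via a
// small deterministic SMO solver, plus the searchlight cross-cue
// decoding engine that calls it for every sphere / fold / permutation.
//
// The solver follows the standard maximal-violating-pair working-set
// selection on the dual problem
//   min 0.5 * a' Q a - sum(a),  0 <= a_i <= C,  sum(y_i a_i) = 0,
// with Q_ij = y_i y_j <x_i, x_j>. Training sets here are tiny (a few
// patterns per class), so a dense kernel and O(n) selection per
// iteration are more than enough; the result is deterministic given
// the input order.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SvcModel {
  std::vector<double> w;
  double b;
  std::vector<double> alpha;
  int iterations;
};

// X: n x p row-major patterns, y: +/-1, same C for both classes.
SvcModel smo_fit(const std::vector<double>& X, int n, int p,
                 const std::vector<int>& y, double C,
                 double eps = 1e-6, int max_iter = 100000) {
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k)
        s += X[(size_t)i * p + k] * X[(size_t)j * p + k];
      K[(size_t)i * n + j] = K[(size_t)j * n + i] = s;
    }
  std::vector<double> a(n, 0.0), G(n, -1.0);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    double gmax = -1e30, gmin = 1e30;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      bool lo = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;
    double quad = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                  2.0 * K[(size_t)i * n + j];
    if (quad <= 0) quad = 1e-12;
    // step along y_i a_i + y_j a_j = const: a_i += y_i d, a_j -= y_j d
    double d = (gmax - gmin) / quad;
    double lo_d, hi_d;
    if (y[i] > 0) { lo_d = -a[i]; hi_d = C - a[i]; }
    else          { lo_d = a[i] - C; hi_d = a[i]; }
    double lo_j, hi_j;  // constraint from a_j
    if (y[j] > 0) { lo_j = a[j] - C; hi_j = a[j]; }
    else          { lo_j = -a[j]; hi_j = C - a[j]; }
    if (lo_j > lo_d) lo_d = lo_j;
    if (hi_j < hi_d) hi_d = hi_j;
    if (d > hi_d) d = hi_d;
    if (d < lo_d) d = lo_d;
    if (std::fabs(d) < 1e-15) break;
    double dai = y[i] * d, daj = -y[j] * d;
    a[i] += dai; a[j] += daj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[(size_t)t * n + i] * dai +
                      y[j] * K[(size_t)t * n + j] * daj);
  }
  // bias from free support vectors, else midpoint of the KKT bounds
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (a[t] > 1e-10 && a[t] < C - 1e-10) { bsum += -y[t] * G[t]; ++nfree; }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else {
    double gmax = -1e30, gmin = 1e30;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      bool lo = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) gmax = v;
      if (lo && v < gmin) gmin = v;
    }
    b = (gmax + gmin) / 2.0;
  }
  SvcModel m;
  m.w.assign(p, 0.0);
  for (int t = 0; t < n; ++t)
    if (a[t] != 0.0)
      for (int k = 0; k < p; ++k)
        m.w[k] += a[t] * y[t] * X[(size_t)t * p + k];
  m.b = b;
  m.alpha = a;
  m.iterations = iter;
  return m;
}

inline int predict1(const SvcModel& m, const double* x, int p) {
  double s = m.b;
  for (int k = 0; k < p; ++k) s += m.w[k] * x[k];
  return s >= 0 ? 1 : -1;
}

}  // namespace

// [[Rcpp::export(name = ".svc_train_cpp")]]
List svc_train_cpp(NumericMatrix X, IntegerVector y, double cost) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> Xr((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) Xr[(size_t)i * p + k] = X(i, k);
  std::vector<int> yy(y.begin(), y.end());
  SvcModel m = smo_fit(Xr, n, p, yy, cost);
  return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()),
                      _["b"] = m.b,
                      _["alpha"] = NumericVector(m.alpha.begin(),
                                                 m.alpha.end()),
                      _["iterations"] = m.iterations);
}

// Cross-cue leave-one-run-out searchlight decoding.
//
// betas: nx*ny*nz*nrun*4 array (condition order: positive_cue1,
// positive_cue2, negative_cue1, negative_cue2). flips: nrow
// label-permutations x nrun matrix of 0/1; within each flipped run the
// positive and negative patterns swap roles (both cues), row of zeros
// = observed labels. Returns an (nx*ny*nz) x nrow(flips) accuracy
// matrix, NA_real_ at centers outside the mask or with fewer than
// min_vox in-mask sphere voxels.
// [[Rcpp::export(name = ".searchlight_cpp")]]
NumericMatrix searchlight_cpp(NumericVector betas, IntegerVector dims,
                              LogicalVector mask, IntegerMatrix offsets,
                              int min_vox, double cost,
                              IntegerMatrix flips) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nrun = dims[3];
  const int nvox = nx * ny * nz;
  const int noff = offsets.nrow();
  const int nflip = flips.nrow();
  const size_t vol = (size_t)nvox;
  NumericMatrix out(nvox, nflip);
  std::fill(out.begin(), out.end(), NA_REAL);

  const int ntrain = 2 * (nrun - 1);
  std::vector<int> sphere; sphere.reserve(noff);
  std::vector<double> train; std::vector<int> ytr(ntrain);
  std::vector<double> testpat;

  for (int cz = 0; cz < nz; ++cz)
   for (int cy = 0; cy < ny; ++cy)
    for (int cx = 0; cx < nx; ++cx) {
      int center = cx + nx * (cy + ny * cz);
      if (!mask[center]) continue;
      sphere.clear();
      for (int o = 0; o < noff; ++o) {
        int x = cx + offsets(o, 0), y = cy + offsets(o, 1),
            z = cz + offsets(o, 2);
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;
        int v = x + nx * (y + ny * z);
        if (mask[v]) sphere.push_back(v);
      }
      const int k = (int)sphere.size();
      if (k < min_vox) continue;

      // pattern(run, cond) -> contiguous copy for locality
      std::vector<double> P((size_t)nrun * 4 * k);
      for (int r = 0; r < nrun; ++r)
        for (int c = 0; c < 4; ++c) {
          double* dst = &P[((size_t)r * 4 + c) * k];
          const double* src = &betas[0];
          for (int t = 0; t < k; ++t)
            dst[t] = src[sphere[t] + vol * (r + (size_t)nrun * c)];
        }

      train.assign((size_t)ntrain * k, 0.0);
      testpat.assign((size_t)2 * k, 0.0);
      for (int f = 0; f < nflip; ++f) {
        double correct = 0.0; int ntest = 0;
        for (int test_run = 0; test_run < nrun; ++test_run)
          for (int dir = 0; dir < 2; ++dir) {
            // train on cue (dir+1), test on the other cue
            int tc = dir, sc = 1 - dir;
            int row = 0;
            for (int r = 0; r < nrun; ++r) {
              if (r == test_run) continue;
              int sw = flips(f, r) ? 2 : 0;  // swap pos<->neg blocks
              int cpos = (0 + sw) % 4 + tc;  // positive_cue(tc+1)
              int cneg = (2 + sw) % 4 + tc;
              std::copy(&P[((size_t)r * 4 + cpos) * k],
                        &P[((size_t)r * 4 + cpos) * k] + k,
                        &train[(size_t)row * k]);
              ytr[row++] = 1;
              std::copy(&P[((size_t)r * 4 + cneg) * k],
                        &P[((size_t)r * 4 + cneg) * k] + k,
                        &train[(size_t)row * k]);
              ytr[row++] = -1;
            }
            SvcModel m = smo_fit(train, ntrain, k, ytr, cost);
            int sw = flips(f, test_run) ? 2 : 0;
            int cpos = (0 + sw) % 4 + sc, cneg = (2 + sw) % 4 + sc;
            correct += predict1(m, &P[((size_t)test_run * 4 + cpos) * k],
                                k) == 1;
            correct += predict1(m, &P[((size_t)test_run * 4 + cneg) * k],
                                k) == -1;
            ntest += 2;
          }
        out(center, f) = correct / ntest;
      }
    }
  return out;
}
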