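#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <array>
using namespace Rcpp;

// Sliding-window Pearson correlation of every row of Y against g, mapped
// through the Fisher r-to-z transform (atanh with |r| clamped to rmax).
//
// Y: V x T matrix (one row per voxel), g: length-T reference series.
// Windows start at 0-based offsets w*step and span L samples; the last
// window must fit entirely: nw = floor((T - L)/step) + 1.
//
// Series are centered on their overall mean first (Pearson is shift
// invariant) and window sums accumulate in double, so the fast
// sum-based formula agrees with a two-pass per-window computation to
// well below 1e-10.
//
// Windows in which either series has zero variance get z = 0; their count
// is returned alongside the matrix.
// [[Rcpp::export]]
List cpp_sliding_z(const NumericMatrix& Y, const NumericVector& g,
                   int L, int step, double rmax) {
  const int V = Y.nrow(), T = Y.ncol();
  if (g.size() != T) stop("length of g must match ncol(Y)");
  if (L < 3 || L > T) stop("window length out of range");
  if (step < 1) stop("step must be >= 1");
  const int nw = (T - L) / step + 1;

  // center g and precompute its cumulative sums
  double gm = 0.0;
  for (int t = 0; t < T; ++t) gm += g[t];
  gm /= T;
  std::vector<double> gc(T), csg(T + 1, 0.0), csgg(T + 1, 0.0);
  for (int t = 0; t < T; ++t) {
    gc[t] = g[t] - gm;
    csg[t + 1] = csg[t] + gc[t];
    csgg[t + 1] = csgg[t] + gc[t] * gc[t];
  }

  NumericMatrix Z(V, nw);
  long long n_zero = 0;
  std::vector<double> yc(T), csy(T + 1), csyy(T + 1), csxy(T + 1);
  csy[0] = csyy[0] = csxy[0] = 0.0;

  for (int v = 0; v < V; ++v) {
    double ym = 0.0;
    for (int t = 0; t < T; ++t) ym += Y(v, t);
    ym /= T;
    for (int t = 0; t < T; ++t) {
      yc[t] = Y(v, t) - ym;
      csy[t + 1] = csy[t] + yc[t];
      csyy[t + 1] = csyy[t] + yc[t] * yc[t];
      csxy[t + 1] = csxy[t] + yc[t] * gc[t];
    }
    for (int w = 0; w < nw; ++w) {
      const int a = w * step, b = a + L;
      const double sy  = csy[b]  - csy[a];
      const double syy = csyy[b] - csyy[a];
      const double sxy = csxy[b] - csxy[a];
      const double sg  = csg[b]  - csg[a];
      const double sgg = csgg[b] - csgg[a];
      const double vy = L * syy - sy * sy;
      const double vg = L * sgg - sg * sg;
      if (vy <= 0.0 || vg <= 0.0) {
        Z(v, w) = 0.0;
        ++n_zero;
        continue;
      }
      double r = (L * sxy - sy * sg) / std::sqrt(vy * vg);
      if (r >  rmax) r =  rmax;
      if (r < -rmax) r = -rmax;
      Z(v, w) = std::atanh(r);
    }
  }
  return List::create(_["z"] = Z, _["n_windows"] = nw,
                      _["n_zero_variance"] = (double)n_zero);
}

// Assemble synthetic voxel time series:
//   y_v(t) = b_v * (1 + m_v * sin(omega*t + phase_v)) * g(t)
//            + sum_p C(v,p) * B(t,p)            (slow drift)
//            + noise_sd * N(0,1)
// with t = 0..T-1 in samples. Uses R's RNG stream; the noise draw order is
// fixed (time-major, voxel-minor) so runs are reproducible from a seed.
// [[Rcpp::export]]
NumericMatrix cpp_simulate_voxels(const NumericVector& g,
                                  const NumericVector& b,
                                  const NumericVector& m,
                                  const NumericVector& phase,
                                  double omega,
                                  const NumericMatrix& drift_basis,
                                  const NumericMatrix& drift_coefs,
                                  double noise_sd) {
  const int T = g.size(), V = b.size();
  if (m.size() != V || phase.size() != V) stop("b, m, phase lengths differ");
  if (drift_basis.nrow() != T || drift_coefs.nrow() != V ||
      drift_basis.ncol() != drift_coefs.ncol())
    stop("drift basis/coefficient shapes inconsistent");
  const int P = drift_basis.ncol();

  std::vector<double> cph(V), sph(V);
  for (int v = 0; v < V; ++v) { cph[v] = std::cos(phase[v]); sph[v] = std::sin(phase[v]); }

  NumericMatrix Y(V, T);
  for (int t = 0; t < T; ++t) {
    const double st = std::sin(omega * t), ct = std::cos(omega * t);
    const double gt = g[t];
    for (int v = 0; v < V; ++v) {
      // sin(omega*t + phase_v) expanded for speed
      const double s = st * cph[v] + ct * sph[v];
      double y = b[v] * (1.0 + m[v] * s) * gt;
      for (int p = 0; p < P; ++p) y += drift_coefs(v, p) * drift_basis(t, p);
      if (noise_sd > 0.0) y += noise_sd * norm_rand();
      Y(v, t) = y;
    }
  }
  return Y;
}

// Label connected components of a 3D logical mask under 6- or
// 26-connectivity. Returns an integer array (same dims) with 0 for
// background and 1..k component labels, assigned in array scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(const LogicalVector& mask,
                                   const IntegerVector& dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != mask.size()) stop("mask length != prod(dims)");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (const auto& o : offs) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}
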