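#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3D array sampling at continuous 0-based voxel indices.
// mode 0 = trilinear, 1 = nearest neighbour; out-of-support -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample3(const NumericVector& vol, const IntegerVector& dim,
                          const NumericMatrix& idx, int mode, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = idx.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  for (int i = 0; i < n; ++i) {
    double x = idx(i, 0), y = idx(i, 1), z = idx(i, 2);
    if (mode == 1) {
      long xi = (long)std::floor(x + 0.5), yi = (long)std::floor(y + 0.5),
           zi = (long)std::floor(z + 0.5);
      if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz)
        out[i] = fill;
      else
        out[i] = v[xi * sx + yi * sy + zi * sz];
    } else {
      const double eps = 1e-6; // voxel-centre coordinates carry float error
      if (x < -eps || y < -eps || z < -eps || x > nx - 1 + eps ||
          y > ny - 1 + eps || z > nz - 1 + eps) {
        out[i] = fill;
        continue;
      }
      if (x < 0) x = 0;
      if (y < 0) y = 0;
      if (z < 0) z = 0;
      if (x > nx - 1) x = nx - 1;
      if (y > ny - 1) y = ny - 1;
      if (z > nz - 1) z = nz - 1;
      long x0 = (long)std::floor(x), y0 = (long)std::floor(y),
           z0 = (long)std::floor(z);
      if (x0 == nx - 1) x0--;
      if (y0 == ny - 1) y0--;
      if (z0 == nz - 1) z0--;
      // degenerate (singleton) axes: clamp the lower corner to 0
      if (x0 < 0) x0 = 0;
      if (y0 < 0) y0 = 0;
      if (z0 < 0) z0 = 0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      if (nx == 1) fx = 0.0;
      if (ny == 1) fy = 0.0;
      if (nz == 1) fz = 0.0;
      long x1 = (nx == 1) ? x0 : x0 + 1, y1 = (ny == 1) ? y0 : y0 + 1,
           z1 = (nz == 1) ? z0 : z0 + 1;
      double c000 = v[x0 + y0 * sy + z0 * sz], c100 = v[x1 + y0 * sy + z0 * sz];
      double c010 = v[x0 + y1 * sy + z0 * sz], c110 = v[x1 + y1 * sy + z0 * sz];
      double c001 = v[x0 + y0 * sy + z1 * sz], c101 = v[x1 + y0 * sy + z1 * sz];
      double c011 = v[x0 + y1 * sy + z1 * sz], c111 = v[x1 + y1 * sy + z1 * sz];
      double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
      double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
      double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
      out[i] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

static inline double bspline3(double t) {
  // cubic B-spline kernel, support [-2, 2]
  double a = std::fabs(t);
  if (a >= 2.0) return 0.0;
  if (a < 1.0) return (4.0 - 6.0 * a * a + 3.0 * a * a * a) / 6.0;
  double b = 2.0 - a;
  return b * b * b / 6.0;
}

// Joint Parzen histogram for Mattes mutual information.
// mov: moving volume; idx: N x 3 continuous 0-based voxel indices into mov
// (already transformed); fbin: 0-based fixed-intensity bin per sample (-1 to
// skip); moving intensity v maps to continuous bin coordinate
// (v - mmin) / mwidth; kernel order 1 (linear) or 3 (cubic B-spline) spreads
// the unit mass over neighbouring bins (clamped at the edges so each sample
// contributes exactly 1). Returns joint counts (nbins x nbins, fixed = rows)
// and the number of in-support samples.
// [[Rcpp::export]]
List cpp_mi_joint(const NumericVector& mov, const IntegerVector& dim,
                  const NumericMatrix& idx, const IntegerVector& fbin,
                  int nbins, double mmin, double mwidth, int order) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = idx.nrow();
  NumericMatrix joint(nbins, nbins);
  const double* v = mov.begin();
  const long sy = nx, sz = (long)nx * ny;
  long inside = 0;
  for (int i = 0; i < n; ++i) {
    if (fbin[i] < 0) continue;
    double x = idx(i, 0), y = idx(i, 1), z = idx(i, 2);
    const double eps = 1e-6;
    if (x < -eps || y < -eps || z < -eps || x > nx - 1 + eps ||
        y > ny - 1 + eps || z > nz - 1 + eps)
      continue;
    if (x < 0) x = 0;
    if (y < 0) y = 0;
    if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    long x0 = (long)std::floor(x), y0 = (long)std::floor(y),
         z0 = (long)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (nx == 1) fx = 0.0;
    if (ny == 1) fy = 0.0;
    if (nz == 1) fz = 0.0;
    long x1 = (nx == 1) ? x0 : x0 + 1, y1 = (ny == 1) ? y0 : y0 + 1,
         z1 = (nz == 1) ? z0 : z0 + 1;
    double c00 = v[x0 + y0 * sy + z0 * sz] * (1 - fx) +
                 v[x1 + y0 * sy + z0 * sz] * fx;
    double c10 = v[x0 + y1 * sy + z0 * sz] * (1 - fx) +
                 v[x1 + y1 * sy + z0 * sz] * fx;
    double c01 = v[x0 + y0 * sy + z1 * sz] * (1 - fx) +
                 v[x1 + y0 * sy + z1 * sz] * fx;
    double c11 = v[x0 + y1 * sy + z1 * sz] * (1 - fx) +
                 v[x1 + y1 * sy + z1 * sz] * fx;
    double val = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                 (c01 * (1 - fy) + c11 * fy) * fz;
    inside++;
    double b = (val - mmin) / mwidth;  // continuous bin coordinate
    int row = fbin[i];
    if (order == 1) {
      int b0 = (int)std::floor(b);
      double w1 = b - b0;
      int ba = b0 < 0 ? 0 : (b0 > nbins - 1 ? nbins - 1 : b0);
      int bb = b0 + 1 < 0 ? 0 : (b0 + 1 > nbins - 1 ? nbins - 1 : b0 + 1);
      joint(row, ba) += 1.0 - w1;
      joint(row, bb) += w1;
    } else {
      int bc = (int)std::floor(b);
      for (int k = bc - 1; k <= bc + 2; ++k) {
        double w = bspline3(b - k);
        if (w <= 0) continue;
        int kk = k < 0 ? 0 : (k > nbins - 1 ? nbins - 1 : k);
        joint(row, kk) += w;
      }
    }
  }
  return List::create(_["joint"] = joint, _["inside"] = (double)inside);
}

// Separable Gaussian blur of a 3D array with per-axis sigma in voxels
// (replicated edges). sigma <= 0 skips the axis.
// [[Rcpp::export]]
NumericVector cpp_blur3(const NumericVector& vol, const IntegerVector& dim,
                        const NumericVector& sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector cur = clone(vol);
  const long sstride[3] = {1, (long)nx, (long)nx * ny};
  const int ndim[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0 || ndim[ax] == 1) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += k[i + r];
    }
    for (auto& w : k) w /= sum;
    NumericVector next(cur.size());
    const long stride = sstride[ax];
    const int nax = ndim[ax];
    // iterate over all lines along axis ax
    long nlines = (long)nx * ny * nz / nax;
    for (long line = 0; line < nlines; ++line) {
      // compute base index of this line
      long rem = line, base = 0;
      for (int d = 0; d < 3; ++d) {
        if (d == ax) continue;
        long coord = rem % ndim[d];
        rem /= ndim[d];
        base += coord * sstride[d];
      }
      for (int p = 0; p < nax; ++p) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int q = p + i;
          if (q < 0) q = 0;
          if (q >= nax) q = nax - 1;
          acc += k[i + r] * cur[base + (long)q * stride];
        }
        next[base + (long)p * stride] = acc;
      }
    }
    cur = next;
  }
  return cur;
}

// Minimum-cost assignment (Hungarian / shortest augmenting path with
// potentials, O(n^2 m)). cost: n x m with n <= m. Returns 1-based column
// assigned to each row.
// [[Rcpp::export]]
IntegerVector cpp_hungarian(const NumericMatrix& cost) {
  const int n = cost.nrow(), m = cost.ncol();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0); // p[j]: row assigned to col j
  const double INF = std::numeric_limits<double>::infinity();
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<bool> used(m + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= m; ++j)
        if (!used[j]) {
          double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
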