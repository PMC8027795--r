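// 3D image-processing kernels: connected-component labelling with
// 6/18/26 connectivity, anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher's separable parabola envelope), greyscale
// reconstruction by dilation (Vincent's hybrid raster + FIFO algorithm),
// marker-based priority-flood watershed, and separable 1D convolution.
//
// All volumes are R arrays with dim = c(nz, ny, nx); the linear index of
// voxel (z, y, x) is z + nz * (y + ny * x), 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Neighbour offsets for a given connectivity (6, 18 or 26).
static void neighbour_offsets(int connectivity,
                              std::vector<int> &dz,
                              std::vector<int> &dy,
                              std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(IntegerVector mask, IntegerVector dim,
                          int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nn; ++k) {
        int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t q = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[q] != 0 && labels[q] == 0) {
          labels[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// 1D squared-distance transform along one line (Felzenszwalb), with
// physical sample spacing s. f holds squared distances on input.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb,
                 int n, double s) {
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double sint;
    while (true) {
      int vk = v[k];
      sint = ((f[q] + s2 * q * q) - (f[vk] + s2 * vk * vk)) /
             (2.0 * s2 * (q - vk));
      if (sint <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = sint;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = s * (q - v[k]);
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// Squared EDT of the foreground (mask != 0) to the nearest background
// voxel, in physical units given per-axis spacing (sz, sy, sx).
// [[Rcpp::export(name = ".edt_sq_3d")]]
NumericVector edt_sq_3d(IntegerVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] != 0 ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      bool any = false;
      for (int z = 0; z < nz; ++z) { f[z] = out[base + z]; if (f[z] != INF) any = true; }
      if (!any) continue;  // all INF: stays INF until another pass sees background
      dt1d(f, d, v, zb, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) out[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      bool any = false;
      for (int y = 0; y < ny; ++y) { f[y] = out[base + (R_xlen_t)nz * y]; if (f[y] != INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nz * y] = d[y];
    }
  // pass along x
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      bool any = false;
      for (int x = 0; x < nx; ++x) { f[x] = out[base + sx * x]; if (f[x] != INF) any = true; }
      if (!any) continue;
      dt1d(f, d, v, zb, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) out[base + sx * x] = d[x];
    }
  out.attr("dim") = dim;
  return out;
}

// Greyscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise is the caller's responsibility).
// [[Rcpp::export(name = ".grey_reconstruct_3d")]]
NumericVector grey_reconstruct_3d(NumericVector marker, NumericVector mask,
                                  IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();

  NumericVector J = clone(marker);

  // raster scan: neighbours already visited in scan order, then reverse
  for (int pass = 0; pass < 2; ++pass) {
    bool fwd = pass == 0;
    for (R_xlen_t ii = 0; ii < n; ++ii) {
      R_xlen_t p = fwd ? ii : (n - 1 - ii);
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      double m = J[p];
      for (int k = 0; k < nn; ++k) {
        // restrict to the scan-causal half of the neighbourhood
        int o = dx[k] * 4 + dy[k] * 2 + dz[k];
        if (fwd ? (o > 0) : (o < 0)) continue;
        int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t q = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (J[q] > m) m = J[q];
      }
      J[p] = std::min(m, mask[p]);
    }
  }

  // FIFO propagation
  std::queue<R_xlen_t> fifo;
  for (R_xlen_t p = 0; p < n; ++p) {
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int k = 0; k < nn; ++k) {
      int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t q = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (J[q] < J[p] && J[q] < mask[q]) { fifo.push(p); break; }
    }
  }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int k = 0; k < nn; ++k) {
      int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t q = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (J[q] < J[p] && J[q] < mask[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dim;
  return J;
}

struct FloodEntry {
  double priority;
  R_xlen_t order;
  R_xlen_t index;
  int label;
};
struct FloodCmp {
  bool operator()(const FloodEntry &a, const FloodEntry &b) const {
    if (a.priority != b.priority) return a.priority < b.priority;  // max-heap
    return a.order > b.order;  // earlier insertion wins ties
  }
};

// Priority-flood watershed: grow `markers` over mask voxels in order of
// decreasing `priority` (e.g. a distance transform). Every mask voxel in
// a marker-bearing component receives exactly one label; no ridge lines.
// [[Rcpp::export(name = ".watershed_flood_3d")]]
IntegerVector watershed_flood_3d(NumericVector priority, IntegerVector markers,
                                 IntegerVector mask, IntegerVector dim,
                                 int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbour_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();

  IntegerVector out(n, 0);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  R_xlen_t order = 0;

  for (R_xlen_t p = 0; p < n; ++p)
    if (markers[p] > 0 && mask[p] != 0) out[p] = markers[p];

  for (R_xlen_t p = 0; p < n; ++p) {
    if (out[p] == 0) continue;
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int k = 0; k < nn; ++k) {
      int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t q = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (mask[q] != 0 && out[q] == 0)
        pq.push({priority[q], order++, q, out[p]});
    }
  }

  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    R_xlen_t p = e.index;
    if (out[p] != 0) continue;
    out[p] = e.label;
    int z = (int)(p % nz);
    int y = (int)((p / nz) % ny);
    int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int k = 0; k < nn; ++k) {
      int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t q = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (mask[q] != 0 && out[q] == 0)
        pq.push({priority[q], order++, q, out[p]});
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Separable 1D convolution along axis (0 = z, 1 = y, 2 = x) with an
// odd-length kernel; boundaries handled by reflection.
// [[Rcpp::export(name = ".convolve_axis_3d")]]
NumericVector convolve_axis_3d(NumericVector vol, IntegerVector dim,
                               NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const int kl = kernel.size();
  const int half = kl / 2;
  NumericVector out(n);

  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nz : (R_xlen_t)nz * ny);

  // iterate over all lines along `axis`
  R_xlen_t nlines = n / len;
  std::vector<double> line(len);
  for (R_xlen_t l = 0; l < nlines; ++l) {
    // base index of this line
    R_xlen_t base;
    if (axis == 0) {
      base = l * nz;
    } else if (axis == 1) {
      R_xlen_t z = l % nz, x = l / nz;
      base = z + (R_xlen_t)nz * ny * x;
    } else {
      base = l;
    }
    for (int i = 0; i < len; ++i) line[i] = vol[base + stride * i];
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      for (int k = 0; k < kl; ++k) {
        int j = i + k - half;
        if (j < 0) j = -j - 1;            // reflect
        if (j >= len) j = 2 * len - j - 1;
        if (j < 0) j = 0;                 // guard for very short lines
        if (j >= len) j = len - 1;
        acc += line[j] * kernel[k];
      }
      out[base + stride * i] = acc;
    }
  }
  out.attr("dim") = dim;
  return out;
}
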