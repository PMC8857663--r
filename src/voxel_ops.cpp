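// Voxel-level primitives shared by the refinement and evaluation code:
// 3-D connected-component labeling, exact anisotropic Euclidean distance
// transform (Felzenszwalb/Huttenlocher lower-envelope method), deterministic
// marker-controlled watershed (priority flood), and 3-D grid resampling.
// All arrays are column-major (R layout), dims = (nx, ny, nz).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline long long lin(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// Neighbor offsets for 6- or 26-connectivity.
static void neighbor_offsets(int connectivity, std::vector<int>& di,
                             std::vector<int>& dj, std::vector<int>& dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manhattan = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manhattan != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, di, dj, dk);
  int nb = (int)di.size();
  std::vector<long long> stack;
  int next_label = 0;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++next_label;
    out[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long long cur = stack.back(); stack.pop_back();
      int k = (int)(cur / ((long long)nx * ny));
      long long rem = cur % ((long long)nx * ny);
      int j = (int)(rem / nx), i = (int)(rem % nx);
      for (int m = 0; m < nb; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        long long q = lin(ii, jj, kk, nx, ny);
        if (mask[q] && out[q] == 0) {
          out[q] = next_label;
          stack.push_back(q);
        }
      }
    }
  }
  return out;
}

// 1-D squared-distance transform over samples at positions x_i = i * sp.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double sp) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * sp;
    double s = 0.0;
    while (true) {
      double xv = v[k] * sp;
      if (std::isinf(f[v[k]]) && std::isinf(f[q])) { s = (xq + xv) / 2.0; }
      else if (std::isinf(f[v[k]])) { s = -INF; }
      else if (std::isinf(f[q])) { s = INF; }
      else s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; s = -INF; break; }
      } else break;
    }
    if (std::isinf(s) && s < 0) continue;  // q replaced the whole envelope
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * sp;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * sp;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Euclidean distance (mm) from every voxel to the nearest seed voxel.
// Voxels are treated as points at index * spacing. All-false seed -> Inf.
// [[Rcpp::export]]
NumericVector edt_to_set_cpp(LogicalVector seed, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n);
  for (long long s = 0; s < n; ++s) d[s] = seed[s] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), row(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[lin(i, j, k, nx, ny)];
      dt1d(f, row, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) d[lin(i, j, k, nx, ny)] = row[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[lin(i, j, k, nx, ny)];
      dt1d(f, row, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[lin(i, j, k, nx, ny)] = row[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[lin(i, j, k, nx, ny)];
      dt1d(f, row, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) d[lin(i, j, k, nx, ny)] = row[k];
    }

  NumericVector out(n);
  for (long long s = 0; s < n; ++s) out[s] = std::isinf(d[s]) ? R_PosInf : std::sqrt(d[s]);
  return out;
}

struct FloodEntry {
  double priority;
  long long order;
  long long idx;
  int label;
};
struct FloodCompare {
  bool operator()(const FloodEntry& a, const FloodEntry& b) const {
    if (a.priority != b.priority) return a.priority > b.priority;  // min-heap
    return a.order > b.order;                                      // FIFO ties
  }
};

// Marker-controlled watershed by priority flooding inside `mask`.
// Lower priority floods first (pass e.g. the negated interior distance).
// Deterministic: ties broken by insertion order.
// [[Rcpp::export]]
IntegerVector watershed_flood_cpp(NumericVector priority, IntegerVector markers,
                                  LogicalVector mask, IntegerVector dims,
                                  int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long n = (long long)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, di, dj, dk);
  int nb = (int)di.size();

  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCompare> pq;
  long long counter = 0;
  for (long long s = 0; s < n; ++s) {
    if (markers[s] > 0 && mask[s]) {
      out[s] = markers[s];
      pq.push(FloodEntry{priority[s], counter++, s, markers[s]});
    }
  }
  while (!pq.empty()) {
    FloodEntry e = pq.top(); pq.pop();
    long long cur = e.idx;
    int k = (int)(cur / ((long long)nx * ny));
    long long rem = cur % ((long long)nx * ny);
    int j = (int)(rem / nx), i = (int)(rem % nx);
    for (int m = 0; m < nb; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      long long q = lin(ii, jj, kk, nx, ny);
      if (mask[q] && out[q] == 0) {
        out[q] = out[cur];
        pq.push(FloodEntry{priority[q], counter++, q, out[q]});
      }
    }
  }
  return out;
}

// Resample a 3-D grid to isotropic spacing t. Voxel i sits at physical
// position i * spacing (voxel-center convention, shared origin).
// nearest = true -> nearest-neighbor (labelmaps); false -> trilinear.
// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector src, IntegerVector sdim,
                                NumericVector sspacing, IntegerVector odim,
                                double t, bool nearest) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((long long)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    double cz = k * t / sspacing[2];
    if (cz < 0) cz = 0; if (cz > nz - 1) cz = nz - 1;
    for (int j = 0; j < oy; ++j) {
      double cy = j * t / sspacing[1];
      if (cy < 0) cy = 0; if (cy > ny - 1) cy = ny - 1;
      for (int i = 0; i < ox; ++i) {
        double cx = i * t / sspacing[0];
        if (cx < 0) cx = 0; if (cx > nx - 1) cx = nx - 1;
        long long o = lin(i, j, k, ox, oy);
        if (nearest) {
          int ri = (int)std::floor(cx + 0.5), rj = (int)std::floor(cy + 0.5),
              rk = (int)std::floor(cz + 0.5);
          if (ri > nx - 1) ri = nx - 1;
          if (rj > ny - 1) rj = ny - 1;
          if (rk > nz - 1) rk = nz - 1;
          out[o] = src[lin(ri, rj, rk, nx, ny)];
        } else {
          int i0 = (int)std::floor(cx), j0 = (int)std::floor(cy), k0 = (int)std::floor(cz);
          int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
              k1 = std::min(k0 + 1, nz - 1);
          double wx = cx - i0, wy = cy - j0, wz = cz - k0;
          double c00 = src[lin(i0, j0, k0, nx, ny)] * (1 - wx) + src[lin(i1, j0, k0, nx, ny)] * wx;
          double c10 = src[lin(i0, j1, k0, nx, ny)] * (1 - wx) + src[lin(i1, j1, k0, nx, ny)] * wx;
          double c01 = src[lin(i0, j0, k1, nx, ny)] * (1 - wx) + src[lin(i1, j0, k1, nx, ny)] * wx;
          double c11 = src[lin(i0, j1, k1, nx, ny)] * (1 - wx) + src[lin(i1, j1, k1, nx, ny)] * wx;
          double c0 = c00 * (1 - wy) + c10 * wy;
          double c1 = c01 * (1 - wy) + c11 * wy;
          out[o] = c0 * (1 - wz) + c1 * wz;
        }
      }
    }
  }
  return out;
}
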