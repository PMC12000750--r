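// 3-D image primitives used by the segmentation workflow: 26-connectivity
// component labeling, anisotropic Euclidean distance transform, seeded
// watershed (priority flood) and neighbourhood maxima detection.
// Volumes are passed as flat vectors with dim = (nz, ny, nx), z fastest,
// matching an R array indexed [z, y, x].
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int i0 = lin(z0, y0, x0, nz, ny);
        if (!mask[i0] || lab[i0]) continue;
        lab[i0] = ++next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back();
          stack.pop_back();
          int z = i % nz, rest = i / nz, y = rest % ny, x = rest / ny;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (!dx && !dy && !dz) continue;
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                int j = lin(zz, yy, xx, nz, ny);
                if (mask[j] && !lab[j]) {
                  lab[j] = next;
                  stack.push_back(j);
                }
              }
        }
      }
  lab.attr("n_objects") = next;
  return lab;
}

// One-dimensional squared-distance transform (Felzenszwalb & Huttenlocher),
// applied separably along each axis with the physical voxel spacing.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double step) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * q - 2.0 * s2 * v[k]);
      if (s <= zb[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  // spacing = (dz, dy, dx) in micrometres; returns distance (um) to the
  // nearest background voxel for every foreground voxel, 0 on background.
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double INF = 1e30;
  NumericVector d(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, out;
  // z pass
  f.resize(nz); out.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[lin(z, y, x, nz, ny)];
      dt1d(f, out, spacing[0]);
      for (int z = 0; z < nz; ++z) d[lin(z, y, x, nz, ny)] = out[z];
    }
  // y pass
  f.resize(ny); out.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[lin(z, y, x, nz, ny)];
      dt1d(f, out, spacing[1]);
      for (int y = 0; y < ny; ++y) d[lin(z, y, x, nz, ny)] = out[y];
    }
  // x pass
  f.resize(nx); out.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d[lin(z, y, x, nz, ny)];
      dt1d(f, out, spacing[2]);
      for (int x = 0; x < nx; ++x) d[lin(z, y, x, nz, ny)] = out[x];
    }
  for (R_xlen_t i = 0; i < d.size(); ++i) d[i] = std::sqrt(d[i]);
  return d;
}

struct WsNode {
  double cost;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.order > b.order;  // FIFO tie-break: deterministic
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector cost, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dims) {
  // Seeded priority-flood watershed: regions grow from seed labels across
  // `mask` in order of increasing `cost`. Ties resolved by insertion order,
  // so the result is deterministic for fixed input.
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector lab(clone(seeds));
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    if (seeds[i] > 0) pq.push({cost[i], order++, (int)i, seeds[i]});
  const int DZ[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DX[6] = {0, 0, 0, 0, 1, -1};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int i = nd.idx;
    int z = i % nz, rest = i / nz, y = rest % ny, x = rest / ny;
    for (int d6 = 0; d6 < 6; ++d6) {
      int zz = z + DZ[d6], yy = y + DY[d6], xx = x + DX[d6];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = lin(zz, yy, xx, nz, ny);
      if (!mask[j] || lab[j] > 0) continue;
      lab[j] = nd.label;
      pq.push({cost[j], order++, j, nd.label});
    }
  }
  return lab;
}

// [[Rcpp::export]]
LogicalVector cpp_local_maxima3d(NumericVector v, LogicalVector mask,
                                 IntegerVector dims) {
  // A foreground voxel is a local maximum when >= all of its 26 neighbours.
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out(v.size(), false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (!mask[i]) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1 && ismax; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                continue;
              if (v[lin(zz, yy, xx, nz, ny)] > v[i]) ismax = false;
            }
        out[i] = ismax;
      }
  return out;
}
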