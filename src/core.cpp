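// 3D image kernels shared by the segmentation and spot-detection stages.
// Array convention (matches the R side): a volume is an R array with
// dim = c(nz, ny, nx); linear index i = z + nz*(y + ny*x), 0-based here.
// All physical distances are in micrometres; callers convert to voxels.

#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
#include <cstdint>
#include <limits>
#include <vector>

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // mirror-without-repeat boundary: (-1 -> 0, -2 -> 1, n -> n-1, ...)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> w(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    w[k + r] = std::exp(-0.5 * (double)k * k / (sigma * sigma));
    s += w[k + r];
  }
  for (double &x : w) x /= s;
  return w;
}

// Separable Gaussian smoothing with per-axis sigma in voxel units.
// sigma_vox below ~1e-8 skips the axis (identity). Axis passes stream over
// contiguous inner blocks so all three directions stay cache-friendly.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = vol.size();
  NumericVector cur = clone(vol);
  NumericVector tmp(n);
  const R_xlen_t stride[3] = {1, nz, (R_xlen_t)nz * ny};
  const int len[3] = {nz, ny, nx};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s < 1e-8) continue;
    std::vector<double> w = gauss_kernel(s);
    int r = ((int)w.size() - 1) / 2;
    const int L = len[ax];
    const R_xlen_t st = stride[ax];       // contiguous inner block length
    const R_xlen_t nblocks = n / (st * L); // outer repetitions
    double *src = REAL(cur), *dst = REAL(tmp);
    if (st == 1) { // contiguous lines: direct convolution
      for (R_xlen_t o = 0; o < nblocks; ++o) {
        const double *in = src + o * L;
        double *out = dst + o * L;
        for (int p = 0; p < L; ++p) {
          double acc = 0.0;
          if (p >= r && p + r < L) {
            const double *ic = in + p - r;
            for (int k = 0; k < 2 * r + 1; ++k) acc += w[k] * ic[k];
          } else {
            for (int k = -r; k <= r; ++k)
              acc += w[k + r] * in[reflect_idx(p + k, L)];
          }
          out[p] = acc;
        }
      }
      std::swap(cur, tmp);
      continue;
    }
    for (R_xlen_t o = 0; o < nblocks; ++o) {
      R_xlen_t base = o * st * L;
      for (int p = 0; p < L; ++p) {
        double *out = dst + base + (R_xlen_t)p * st;
        for (R_xlen_t t = 0; t < st; ++t) out[t] = 0.0;
        for (int k = -r; k <= r; ++k) {
          int q = reflect_idx(p + k, L);
          const double *in = src + base + (R_xlen_t)q * st;
          const double wk = w[k + r];
          for (R_xlen_t t = 0; t < st; ++t) out[t] += wk * in[t];
        }
      }
    }
    std::swap(cur, tmp);
  }
  cur.attr("dim") = dim;
  return cur;
}

// Local mean over a box window (2*half+1 voxels per axis), window clipped at
// the volume boundary (mean over the in-bounds part). Integral-image based.
// [[Rcpp::export]]
NumericVector cpp_local_mean(NumericVector vol, IntegerVector dim,
                             IntegerVector half) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int hz = half[0], hy = half[1], hx = half[2];
  // integral image with one layer of padding
  const R_xlen_t pz = nz + 1, py = ny + 1, px = nx + 1;
  std::vector<double> S((size_t)(pz * py * px), 0.0);
  auto sidx = [&](int z, int y, int x) -> R_xlen_t {
    return z + pz * (y + py * (R_xlen_t)x);
  };
  for (int x = 1; x <= nx; ++x)
    for (int y = 1; y <= ny; ++y)
      for (int z = 1; z <= nz; ++z) {
        double v = vol[(z - 1) + (R_xlen_t)nz * ((y - 1) + (R_xlen_t)ny * (x - 1))];
        S[sidx(z, y, x)] = v + S[sidx(z - 1, y, x)] + S[sidx(z, y - 1, x)] +
                           S[sidx(z, y, x - 1)] - S[sidx(z - 1, y - 1, x)] -
                           S[sidx(z - 1, y, x - 1)] - S[sidx(z, y - 1, x - 1)] +
                           S[sidx(z - 1, y - 1, x - 1)];
      }
  NumericVector out(vol.size());
  for (int x = 0; x < nx; ++x) {
    int x0 = std::max(0, x - hx), x1 = std::min(nx - 1, x + hx);
    for (int y = 0; y < ny; ++y) {
      int y0 = std::max(0, y - hy), y1 = std::min(ny - 1, y + hy);
      for (int z = 0; z < nz; ++z) {
        int z0 = std::max(0, z - hz), z1 = std::min(nz - 1, z + hz);
        double sum = S[sidx(z1 + 1, y1 + 1, x1 + 1)] -
                     S[sidx(z0, y1 + 1, x1 + 1)] - S[sidx(z1 + 1, y0, x1 + 1)] -
                     S[sidx(z1 + 1, y1 + 1, x0)] + S[sidx(z0, y0, x1 + 1)] +
                     S[sidx(z0, y1 + 1, x0)] + S[sidx(z1 + 1, y0, x0)] -
                     S[sidx(z0, y0, x0)];
        double cnt = (double)(z1 - z0 + 1) * (y1 - y0 + 1) * (x1 - x0 + 1);
        out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = sum / cnt;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

struct UF {
  std::vector<int> p;
  int find(int a) {
    while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; }
    return a;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) p[std::max(a, b)] = std::min(a, b);
  }
};

// 26-connected component labelling, labels assigned in raster-scan order of
// each component's first voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  UF uf;
  uf.p.push_back(0); // label 0 unused
  int next = 1;
  // offsets to already-scanned 26-neighbours (negative linear offset)
  std::vector<std::array<int, 3>> prev;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        long off = dz + (long)nz * (dy + (long)ny * dx);
        if (off < 0) prev.push_back({dz, dy, dx});
      }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i]) continue;
        int best = 0;
        for (auto &d : prev) {
          int zz = z + d[0], yy = y + d[1], xx = x + d[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          int l = lab[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
          if (l > 0) {
            if (best == 0) best = l;
            else uf.unite(best, l);
            if (l < best) best = l;
          }
        }
        if (best == 0) {
          uf.p.push_back(next);
          lab[i] = next++;
        } else {
          lab[i] = best;
        }
      }
  // second pass: roots renumbered in scan order of first occurrence
  std::vector<int> remap(next, 0);
  int out_next = 1;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (lab[i] == 0) continue;
        int r = uf.find(lab[i]);
        if (remap[r] == 0) remap[r] = out_next++;
        lab[i] = remap[r];
      }
  lab.attr("dim") = dim;
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with spacing h.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double h2, std::vector<int> &v, std::vector<double> &zb) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (f[v[k]] == INF) { // previous parabola at +inf: replace
        if (k == 0) { v[0] = q; zb[0] = -INF; zb[1] = INF; break; }
        --k;
        continue;
      }
      s = ((f[q] + (double)q * q * h2) - (f[v[k]] + (double)v[k] * v[k] * h2)) /
          (2.0 * h2 * (q - v[k]));
      if (s <= zb[k]) { --k; continue; }
      ++k;
      v[k] = q;
      zb[k] = s;
      zb[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq * h2 + f[v[k]];
  }
}

// Euclidean distance (um) from each foreground voxel to the nearest
// background voxel; anisotropic voxel spacing. Voxels outside the grid do
// not count as background (distance measured within the grid).
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = mask.size();
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;
  const int len[3] = {nz, ny, nx};
  const int stride[3] = {1, nz, nz * ny};
  int maxlen = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxlen), d(maxlen), zb(maxlen + 1);
  std::vector<int> v(maxlen);
  for (int ax = 0; ax < 3; ++ax) {
    int L = len[ax], st = stride[ax];
    double h2 = voxel[ax] * voxel[ax];
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          int pos3[3] = {z, y, x};
          if (pos3[ax] != 0) continue;
          R_xlen_t base = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
          bool allinf = true, allzero = true;
          for (int p = 0; p < L; ++p) {
            f[p] = g[base + (R_xlen_t)p * st];
            if (f[p] != INF) allinf = false;
            if (f[p] != 0.0) allzero = false;
          }
          if (allzero) continue;
          if (allinf) continue; // stays INF, resolved along another axis
          dt1d(f, d, L, h2, v, zb);
          for (int p = 0; p < L; ++p) g[base + (R_xlen_t)p * st] = d[p];
        }
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

struct WsItem {
  double h;
  long long ord;
  int idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsItem &a, const WsItem &b) const {
    if (a.h != b.h) return a.h > b.h; // min-heap on height
    return a.ord > b.ord;             // FIFO on ties
  }
};

// Seeded watershed: ascending flood of `height` from labelled seeds,
// restricted to `mask`. Ties broken by insertion order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = height.size();
  IntegerVector lab(n, 0);
  std::priority_queue<WsItem, std::vector<WsItem>, WsCmp> pq;
  long long ord = 0;
  auto push_nb = [&](int z, int y, int x, int l) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (mask[j] && lab[j] == 0)
            pq.push({height[j], ord++, (int)j, l});
        }
  };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (mask[i] && seeds[i] > 0) lab[i] = seeds[i];
      }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (lab[i] > 0) push_nb(z, y, x, lab[i]);
      }
  while (!pq.empty()) {
    WsItem it = pq.top();
    pq.pop();
    if (lab[it.idx] != 0) continue;
    lab[it.idx] = it.lab;
    int x = it.idx / (nz * ny);
    int rem = it.idx % (nz * ny);
    int y = rem / nz, z = rem % nz;
    push_nb(z, y, x, it.lab);
  }
  lab.attr("dim") = dim;
  return lab;
}

// Voxels that are >= all of their in-grid, in-mask 26-neighbours.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector field, LogicalVector mask,
                               IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector out(field.size(), FALSE);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[i]) continue;
        double v = field[i];
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1 && ismax; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 ||
                  xx >= nx)
                continue;
              R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (mask[j] && field[j] > v) ismax = false;
            }
        out[i] = ismax;
      }
  out.attr("dim") = dim;
  return out;
}

// For every pair of 26-adjacent labels, the saddle height:
// max over adjacent voxel pairs (u in A, v in B) of min(I[u], I[v]).
// [[Rcpp::export]]
DataFrame cpp_region_saddles(IntegerVector labels, NumericVector intensity,
                             IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  std::map<std::pair<int, int>, double> sad;
  // forward 26-neighbours only (each unordered voxel pair visited once)
  std::vector<std::array<int, 3>> fwd;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        long off = dz + (long)nz * (dy + (long)ny * dx);
        if (off > 0) fwd.push_back({dz, dy, dx});
      }
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        int la = labels[i];
        if (la == 0) continue;
        for (auto &d : fwd) {
          int zz = z + d[0], yy = y + d[1], xx = x + d[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          int lb = labels[j];
          if (lb == 0 || lb == la) continue;
          std::pair<int, int> key(std::min(la, lb), std::max(la, lb));
          double h = std::min(intensity[i], intensity[j]);
          auto it = sad.find(key);
          if (it == sad.end()) sad[key] = h;
          else if (h > it->second) it->second = h;
        }
      }
  int m = (int)sad.size();
  IntegerVector a(m), b(m);
  NumericVector s(m);
  int k = 0;
  for (auto &kv : sad) {
    a[k] = kv.first.first;
    b[k] = kv.first.second;
    s[k] = kv.second;
    ++k;
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["saddle"] = s);
}

// Binary render of axis-aligned ellipsoids (centers/semi-axes in um, rows
// ordered z,y,x). Voxel center of index i is (i + 0.5) * voxel.
// [[Rcpp::export]]
NumericVector cpp_fill_ellipsoids(IntegerVector dim, NumericMatrix centers,
                                  NumericMatrix semiaxes,
                                  NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out((R_xlen_t)nz * ny * nx, 0.0);
  for (int k = 0; k < centers.nrow(); ++k) {
    double cz = centers(k, 0), cy = centers(k, 1), cx = centers(k, 2);
    double az = semiaxes(k, 0), ay = semiaxes(k, 1), ax = semiaxes(k, 2);
    int z0 = std::max(0, (int)std::floor((cz - az) / voxel[0] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + az) / voxel[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - ay) / voxel[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + ay) / voxel[1] - 0.5));
    int x0 = std::max(0, (int)std::floor((cx - ax) / voxel[2] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + ax) / voxel[2] - 0.5));
    for (int x = x0; x <= x1; ++x) {
      double ddx = ((x + 0.5) * voxel[2] - cx) / ax;
      for (int y = y0; y <= y1; ++y) {
        double ddy = ((y + 0.5) * voxel[1] - cy) / ay;
        for (int z = z0; z <= z1; ++z) {
          double ddz = ((z + 0.5) * voxel[0] - cz) / az;
          if (ddz * ddz + ddy * ddy + ddx * ddx <= 1.0)
            out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = 1.0;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Adds anisotropic Gaussian puncta (amplitude at center, sigma in um per
// axis, truncated at 4 sigma) at the given um centers. Modifies a copy.
// [[Rcpp::export]]
NumericVector cpp_add_spots(NumericVector vol, IntegerVector dim,
                            NumericMatrix centers, NumericVector sigma,
                            double amplitude, NumericVector voxel) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  for (int k = 0; k < centers.nrow(); ++k) {
    double cz = centers(k, 0), cy = centers(k, 1), cx = centers(k, 2);
    int z0 = std::max(0, (int)std::floor((cz - 4 * sigma[0]) / voxel[0] - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + 4 * sigma[0]) / voxel[0] - 0.5));
    int y0 = std::max(0, (int)std::floor((cy - 4 * sigma[1]) / voxel[1] - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + 4 * sigma[1]) / voxel[1] - 0.5));
    int x0 = std::max(0, (int)std::floor((cx - 4 * sigma[2]) / voxel[2] - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + 4 * sigma[2]) / voxel[2] - 0.5));
    for (int x = x0; x <= x1; ++x) {
      double ex = (x + 0.5) * voxel[2] - cx;
      double qx = ex * ex / (2.0 * sigma[2] * sigma[2]);
      for (int y = y0; y <= y1; ++y) {
        double ey = (y + 0.5) * voxel[1] - cy;
        double qy = ey * ey / (2.0 * sigma[1] * sigma[1]);
        for (int z = z0; z <= z1; ++z) {
          double ez = (z + 0.5) * voxel[0] - cz;
          double q = qx + qy + ez * ez / (2.0 * sigma[0] * sigma[0]);
          if (q <= 8.0)
            out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] +=
                amplitude * std::exp(-q);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// One-pass finish of a rendered channel: add constant background and
// seeded Gaussian noise, clip to [0, clipmax], round to integer grey
// levels. Same RNG stream as cpp_gauss_noise.
// [[Rcpp::export]]
NumericVector cpp_finish_channel(NumericVector vol, double background,
                                 double sd, double seed, double clipmax) {
  const R_xlen_t n = vol.size();
  NumericVector out = clone(vol);
  uint64_t state = (uint64_t)seed;
  auto next = [&]() -> uint64_t {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  };
  auto unif = [&]() -> double {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  };
  const double TWOPI = 6.283185307179586476925286766559;
  R_xlen_t i = 0;
  while (i < n) {
    double g1 = 0.0, g2 = 0.0;
    if (sd > 0) {
      double u1 = unif(), u2 = unif();
      double rr = std::sqrt(-2.0 * std::log(u1));
      g1 = sd * rr * std::cos(TWOPI * u2);
      g2 = sd * rr * std::sin(TWOPI * u2);
    }
    double v = out[i] + background + g1;
    out[i] = std::nearbyint(std::min(std::max(v, 0.0), clipmax));
    ++i;
    if (i < n) {
      v = out[i] + background + g2;
      out[i] = std::nearbyint(std::min(std::max(v, 0.0), clipmax));
      ++i;
    }
  }
  out.attr("dim") = vol.attr("dim");
  return out;
}

// Type-7 quantile via nth_element (avoids a full sort of the volume).
// [[Rcpp::export]]
double cpp_quantile7(NumericVector x, double prob) {
  const R_xlen_t n = x.size();
  if (n == 0) return NA_REAL;
  double h = (double)(n - 1) * prob;
  R_xlen_t lo = (R_xlen_t)std::floor(h);
  R_xlen_t hi = std::min(lo + 1, n - 1);
  std::vector<double> v(x.begin(), x.end());
  std::nth_element(v.begin(), v.begin() + lo, v.end());
  double a = v[lo];
  if (hi == lo) return a;
  double b = *std::min_element(v.begin() + lo + 1, v.end());
  return a + (h - lo) * (b - a);
}

// One-pass 0-based inclusive bounding boxes per label:
// rows = labels 1..K, cols = z0,z1,y0,y1,x0,x1 (-1 rows for absent labels).
// [[Rcpp::export]]
IntegerMatrix cpp_label_bboxes(IntegerVector labels, IntegerVector dim,
                               int nlab) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerMatrix bb(nlab, 6);
  for (int l = 0; l < nlab; ++l) {
    bb(l, 0) = bb(l, 2) = bb(l, 4) = -1;
    bb(l, 1) = bb(l, 3) = bb(l, 5) = -1;
  }
  R_xlen_t i = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z, ++i) {
        int l = labels[i];
        if (l <= 0 || l > nlab) continue;
        int r = l - 1;
        if (bb(r, 0) < 0) {
          bb(r, 0) = bb(r, 1) = z;
          bb(r, 2) = bb(r, 3) = y;
          bb(r, 4) = bb(r, 5) = x;
        } else {
          if (z < bb(r, 0)) bb(r, 0) = z;
          if (z > bb(r, 1)) bb(r, 1) = z;
          if (y < bb(r, 2)) bb(r, 2) = y;
          if (y > bb(r, 3)) bb(r, 3) = y;
          if (x < bb(r, 4)) bb(r, 4) = x;
          if (x > bb(r, 5)) bb(r, 5) = x;
        }
      }
  return bb;
}

// Seeded Gaussian noise (splitmix64 + Box-Muller); fast and reproducible
// for a given integer seed.
// [[Rcpp::export]]
NumericVector cpp_gauss_noise(int n, double sd, double seed) {
  NumericVector out(n);
  uint64_t state = (uint64_t)seed;
  auto next = [&]() -> uint64_t {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  };
  auto unif = [&]() -> double {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  };
  const double TWOPI = 6.283185307179586476925286766559;
  int i = 0;
  while (i < n) {
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    out[i++] = sd * r * std::cos(TWOPI * u2);
    if (i < n) out[i++] = sd * r * std::sin(TWOPI * u2);
  }
  return out;
}
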