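// Voxel-grid kernels: connected components, greyscale reconstruction,
// regional maxima, marker-controlled watershed flooding, separable Gaussian
// blur and squared Euclidean distance transform.
//
// All arrays are R arrays of dim (nz, ny, nx), column-major, so linear index
// idx = z + nz * (y + ny * x) with 0-based z, y, x.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <limits>

using namespace Rcpp;

// neighbor offsets (dz, dy, dx) for face (6), face+edge (18), full (26)
static void neighbor_offsets(int connectivity, std::vector<int>& dz,
                             std::vector<int>& dy, std::vector<int>& dx) {
  dz.clear(); dy.clear(); dx.clear();
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

// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p % nz);
      int y = (int)((p / nz) % ny);
      int x = (int)(p / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Greyscale reconstruction by dilation of `marker` under `ceiling`, restricted
// to `region` (voxels outside region never participate). Vincent's hybrid
// algorithm: forward + backward raster scan, then FIFO queue propagation.
// [[Rcpp::export(name = ".grey_reconstruct")]]
NumericVector grey_reconstruct(NumericVector marker, NumericVector ceiling,
                               LogicalVector region, IntegerVector dims,
                               int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  NumericVector J(n);
  for (R_xlen_t i = 0; i < n; ++i)
    J[i] = region[i] ? std::min(marker[i], ceiling[i]) : R_NegInf;

  // forward scan: neighbors with lower linear index
  for (R_xlen_t p = 0; p < n; ++p) {
    if (!region[p]) continue;
    int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
    double m = J[p];
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (q < p && region[q] && J[q] > m) m = J[q];
    }
    J[p] = std::min(m, ceiling[p]);
  }
  // backward scan + queue seeding
  std::queue<R_xlen_t> fifo;
  for (R_xlen_t p = n - 1; p >= 0; --p) {
    if (region[p]) {
      int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
      double m = J[p];
      bool enqueue = false;
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (q > p && region[q] && J[q] > m) m = J[q];
      }
      J[p] = std::min(m, ceiling[p]);
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (q > p && region[q] && J[q] < J[p] && J[q] < ceiling[q]) {
          enqueue = true; break;
        }
      }
      if (enqueue) fifo.push(p);
    }
    if (p == 0) break;
  }
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!region[q]) continue;
      if (J[q] < J[p] && ceiling[q] != J[q]) {
        J[q] = std::min(J[p], ceiling[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dims;
  return J;
}

// Regional-maximum plateaus of img within region: returns plateau labels
// 1..K on regional maxima, 0 elsewhere. A plateau is a connected component of
// equal value; it is a regional maximum iff no member has an in-region
// neighbor of strictly greater value.
// [[Rcpp::export(name = ".regional_maxima")]]
IntegerVector regional_maxima(NumericVector img, LogicalVector region,
                              IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack, members;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!region[i] || lab[i] != 0) continue;
    const double v = img[i];
    bool is_max = true;
    ++next;
    lab[i] = next;
    stack.clear(); members.clear();
    stack.push_back(i); members.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (!region[q]) continue;
        if (img[q] > v) is_max = false;
        else if (img[q] == v && lab[q] == 0) {
          lab[q] = next; stack.push_back(q); members.push_back(q);
        }
      }
    }
    if (!is_max) {
      for (size_t k = 0; k < members.size(); ++k) lab[members[k]] = -1;
      --next;
      // relabel later plateaus compactly: mark as visited with -1, fix below
    }
  }
  // compress: -1 (visited non-max) -> 0; renumber positives 1..K in first-seen order
  std::vector<int> remap;
  remap.push_back(0);
  int K = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] < 0) { lab[i] = 0; continue; }
    if (lab[i] > 0) {
      if (lab[i] >= (int)remap.size()) remap.resize(lab[i] + 1, 0);
      if (remap[lab[i]] == 0) remap[lab[i]] = ++K;
      lab[i] = remap[lab[i]];
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Marker-controlled watershed: flood `priority` (ascending) from `markers`
// within `region`. Deterministic: min-heap ordered by (priority, insertion
// order); seeds inserted in linear-index order with neighbors in fixed order.
// Every region voxel receives a label (markers assumed non-empty in region).
struct WsNode {
  double p; long long ord; R_xlen_t idx; int lab;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.p != b.p) return a.p > b.p;
    return a.ord > b.ord;
  }
};

// [[Rcpp::export(name = ".watershed_flood")]]
IntegerVector watershed_flood(NumericVector priority, IntegerVector markers,
                              LogicalVector region, IntegerVector dims,
                              int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> heap;
  long long ord = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (region[i] && markers[i] > 0) lab[i] = markers[i];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!region[i] || lab[i] == 0) continue;
    int z = (int)(i % nz), y = (int)((i / nz) % ny), x = (int)(i / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (region[q] && lab[q] == 0)
        heap.push(WsNode{priority[q], ord++, q, lab[i]});
    }
  }
  while (!heap.empty()) {
    WsNode nd = heap.top(); heap.pop();
    if (lab[nd.idx] != 0) continue;
    lab[nd.idx] = nd.lab;
    R_xlen_t p = nd.idx;
    int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (region[q] && lab[q] == 0)
        heap.push(WsNode{priority[q], ord++, q, nd.lab});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// separable Gaussian blur, reflecting boundaries; sigma per axis in voxels
// [[Rcpp::export(name = ".gauss_blur3")]]
NumericVector gauss_blur3(NumericVector img, IntegerVector dims,
                          NumericVector sigma_vox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out = clone(img);
  double* v = REAL(out);
  const R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  const R_xlen_t lens[3] = {(R_xlen_t)nz, (R_xlen_t)ny, (R_xlen_t)nx};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    double tot = 0.0;
    for (int k = -r; k <= r; ++k) {
      kern[k + r] = std::exp(-0.5 * (double)k * k / (s * s));
      tot += kern[k + r];
    }
    for (size_t k = 0; k < kern.size(); ++k) kern[k] /= tot;
    const R_xlen_t stride = strides[ax], len = lens[ax];
    const R_xlen_t nlines = n / len;
    std::vector<double> line((size_t)len);
    std::vector<double> dst;
    for (R_xlen_t li = 0; li < nlines; ++li) {
      // compute base offset of line li for this axis
      R_xlen_t base;
      if (ax == 0) {
        base = li * nz;                       // li enumerates (y, x)
      } else if (ax == 1) {
        R_xlen_t z = li % nz, x = li / nz;
        base = z + (R_xlen_t)nz * ny * x;
      } else {
        base = li;                            // li enumerates (z, y)
      }
      for (R_xlen_t i = 0; i < len; ++i) line[(size_t)i] = v[base + i * stride];
      const int rr = r;
      for (R_xlen_t i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = -rr; k <= rr; ++k) {
          R_xlen_t j = i + k;
          if (j < 0) j = -j;
          if (j >= len) j = 2 * (len - 1) - j;
          if (j < 0) j = 0;
          acc += kern[k + rr] * line[(size_t)j];
        }
        v[base + i * stride] = acc;
      }
    }
    (void)dst; (void)line;
  }
  out.attr("dim") = dims;
  return out;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher)
static void edt_1d(std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& vtx, std::vector<double>& zbd, int n) {
  int k = 0;
  vtx[0] = 0;
  zbd[0] = -std::numeric_limits<double>::infinity();
  zbd[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = vtx[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * q - 2.0 * p);
      if (s <= zbd[k]) { --k; } else break;
    }
    ++k;
    vtx[k] = q;
    zbd[k] = s;
    zbd[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbd[k + 1] < q) ++k;
    int p = vtx[k];
    d[q] = (q - (double)p) * (q - (double)p) + f[p];
  }
}

// squared Euclidean distance (in voxels) from each true voxel to the nearest
// false voxel; out-of-grid is treated as inside (distance limited by in-grid
// background only)
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = 1e30;
  NumericVector out(n);
  double* v = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = mask[i] ? INF : 0.0;
  const R_xlen_t strides[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  const int lens[3] = {nz, ny, nx};
  int maxlen = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxlen), d(maxlen), zbd(maxlen + 1);
  std::vector<int> vtx(maxlen);
  for (int ax = 0; ax < 3; ++ax) {
    const R_xlen_t stride = strides[ax];
    const int len = lens[ax];
    const R_xlen_t nlines = n / len;
    for (R_xlen_t li = 0; li < nlines; ++li) {
      R_xlen_t base;
      if (ax == 0) base = li * nz;
      else if (ax == 1) { R_xlen_t z = li % nz, x = li / nz; base = z + (R_xlen_t)nz * ny * x; }
      else base = li;
      for (int i = 0; i < len; ++i) f[i] = v[base + (R_xlen_t)i * stride];
      edt_1d(f, d, vtx, zbd, len);
      for (int i = 0; i < len; ++i) v[base + (R_xlen_t)i * stride] = d[i];
    }
  }
  out.attr("dim") = dims;
  return out;
}

// boundary contact areas between a given label and its neighbors (face
// adjacency); returns table of (neighbor label, shared faces) for voxels of
// `target` against all other positive labels
// [[Rcpp::export(name = ".label_contact")]]
IntegerMatrix label_contact(IntegerVector lab, IntegerVector dims, int target) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::map<int, int> counts;
  const int DZ[6] = {1, -1, 0, 0, 0, 0};
  const int DY[6] = {0, 0, 1, -1, 0, 0};
  const int DX[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t p = 0; p < n; ++p) {
    if (lab[p] != target) continue;
    int z = (int)(p % nz), y = (int)((p / nz) % ny), x = (int)(p / ((R_xlen_t)nz * ny));
    for (int k = 0; k < 6; ++k) {
      int zz = z + DZ[k], yy = y + DY[k], xx = x + DX[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t q = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (lab[q] > 0 && lab[q] != target) counts[lab[q]]++;
    }
  }
  IntegerMatrix res((int)counts.size(), 2);
  int i = 0;
  for (std::map<int, int>::iterator it = counts.begin(); it != counts.end(); ++it) {
    res(i, 0) = it->first;
    res(i, 1) = it->second;
    ++i;
  }
  return res;
}
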