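#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Volumes are column-major R arrays with dim = (ny, nx, nz); linear index
// i = y + ny*x + ny*nx*z (0-based here).

static inline int reflect_idx(int i, int n) {
  // mirror boundary without repeating the edge sample twice in a row
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// 26- or 6-connected component labeling of a logical mask.
// [[Rcpp::export]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity = 26) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector out(n, 0);

  std::vector<int> dy, dx, dz;
  for (int z = -1; z <= 1; ++z)
    for (int x = -1; x <= 1; ++x)
      for (int y = -1; y <= 1; ++y) {
        if (y == 0 && x == 0 && z == 0) continue;
        int manh = std::abs(y) + std::abs(x) + std::abs(z);
        if (connectivity == 6 && manh != 1) continue;
        dy.push_back(y); dx.push_back(x); dz.push_back(z);
      }
  const int nn = (int)dy.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++next;
    out[s] = next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int y = (int)(v % ny);
      int x = (int)((v / ny) % nx);
      int z = (int)(v / ((R_xlen_t)ny * nx));
      for (int k = 0; k < nn; ++k) {
        int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
        R_xlen_t w = yy + (R_xlen_t)ny * xx + (R_xlen_t)ny * nx * zz;
        if (mask[w] && out[w] == 0) { out[w] = next; q.push(w); }
      }
    }
  }
  return out;
}

static void run_minmax_axis(std::vector<double> &v, int ny, int nx, int nz,
                            int axis, int radius, bool take_max) {
  if (radius <= 0) return;
  int len, stride, nlines;
  if (axis == 0)      { len = ny; stride = 1; }
  else if (axis == 1) { len = nx; stride = ny; }
  else                { len = nz; stride = ny * nx; }
  std::vector<double> line(len), res(len);
  R_xlen_t total = (R_xlen_t)ny * nx * nz;
  nlines = (int)(total / len);
  for (int l = 0; l < nlines; ++l) {
    // compute base offset of this line
    R_xlen_t base;
    if (axis == 0) {
      int x = l % nx, z = l / nx;
      base = (R_xlen_t)ny * x + (R_xlen_t)ny * nx * z;
    } else if (axis == 1) {
      int y = l % ny, z = l / ny;
      base = y + (R_xlen_t)ny * nx * z;
    } else {
      base = l; // y + ny*x enumerates all (y,x)
    }
    for (int i = 0; i < len; ++i) line[i] = v[base + (R_xlen_t)i * stride];
    for (int i = 0; i < len; ++i) {
      int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
      double m = line[lo];
      for (int j = lo + 1; j <= hi; ++j)
        m = take_max ? std::max(m, line[j]) : std::min(m, line[j]);
      res[i] = m;
    }
    for (int i = 0; i < len; ++i) v[base + (R_xlen_t)i * stride] = res[i];
  }
}

// Grayscale erosion/dilation by a centred box of half-widths radius = (ry, rx, rz).
// Windows are clipped at the image border (border values do not propagate inward).
// [[Rcpp::export]]
NumericVector box_morph(NumericVector img, IntegerVector dim, IntegerVector radius,
                        bool dilate) {
  std::vector<double> v(img.begin(), img.end());
  for (int axis = 0; axis < 3; ++axis)
    run_minmax_axis(v, dim[0], dim[1], dim[2], axis, radius[axis], dilate);
  NumericVector out(v.begin(), v.end());
  return out;
}

// Binary erosion/dilation by an explicit offset list (rows of (dy, dx, dz)).
// Outside the image counts as background.
// [[Rcpp::export]]
LogicalVector offset_morph(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets,
                           bool dilate) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  const int no = offsets.nrow();
  LogicalVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    int y = (int)(v % ny);
    int x = (int)((v / ny) % nx);
    int z = (int)(v / ((R_xlen_t)ny * nx));
    bool acc = dilate ? false : true;
    for (int k = 0; k < no; ++k) {
      int yy = y + offsets(k, 0), xx = x + offsets(k, 1), zz = z + offsets(k, 2);
      bool val;
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) val = false;
      else val = mask[yy + (R_xlen_t)ny * xx + (R_xlen_t)ny * nx * zz];
      if (dilate) { if (val) { acc = true; break; } }
      else        { if (!val) { acc = false; break; } }
    }
    out[v] = acc;
  }
  return out;
}

// Separable Gaussian blur; sigma in voxels per axis; mirror boundary.
// [[Rcpp::export]]
NumericVector gauss_blur3(NumericVector img, IntegerVector dim, NumericVector sigma) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  std::vector<double> v(img.begin(), img.end());
  int dims[3] = {ny, nx, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.5 * s);
    std::vector<double> ker(2 * r + 1);
    double tot = 0.0;
    for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (s * s)); tot += ker[i + r]; }
    for (double &k : ker) k /= tot;

    int len = dims[axis];
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? ny : (R_xlen_t)ny * nx;
    R_xlen_t total = (R_xlen_t)ny * nx * nz;
    int nlines = (int)(total / len);
    std::vector<double> line(len), res(len);
    for (int l = 0; l < nlines; ++l) {
      R_xlen_t base;
      if (axis == 0) {
        int x = l % nx, z = l / nx;
        base = (R_xlen_t)ny * x + (R_xlen_t)ny * nx * z;
      } else if (axis == 1) {
        int y = l % ny, z = l / ny;
        base = y + (R_xlen_t)ny * nx * z;
      } else {
        base = l;
      }
      for (int i = 0; i < len; ++i) line[i] = v[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) acc += ker[j + r] * line[reflect_idx(i + j, len)];
        res[i] = acc;
      }
      for (int i = 0; i < len; ++i) v[base + (R_xlen_t)i * stride] = res[i];
    }
  }
  NumericVector out(v.begin(), v.end());
  return out;
}

// Multi-source breadth-first label growth: every TRUE voxel of `mask` is
// assigned the label of its nearest (BFS-metric) seed; seeds are the nonzero
// entries of `labels` and must lie inside `mask`.
// [[Rcpp::export]]
IntegerVector grow_labels(IntegerVector labels, LogicalVector mask, IntegerVector dim,
                          int connectivity = 6) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector out = clone(labels);

  std::vector<int> dy, dx, dz;
  for (int z = -1; z <= 1; ++z)
    for (int x = -1; x <= 1; ++x)
      for (int y = -1; y <= 1; ++y) {
        if (y == 0 && x == 0 && z == 0) continue;
        int manh = std::abs(y) + std::abs(x) + std::abs(z);
        if (connectivity == 6 && manh != 1) continue;
        dy.push_back(y); dx.push_back(x); dz.push_back(z);
      }
  const int nn = (int)dy.size();

  std::queue<R_xlen_t> q;
  for (R_xlen_t v = 0; v < n; ++v)
    if (out[v] != 0 && mask[v]) q.push(v);
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int y = (int)(v % ny);
    int x = (int)((v / ny) % nx);
    int z = (int)(v / ((R_xlen_t)ny * nx));
    for (int k = 0; k < nn; ++k) {
      int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      R_xlen_t w = yy + (R_xlen_t)ny * xx + (R_xlen_t)ny * nx * zz;
      if (mask[w] && out[w] == 0) { out[w] = out[v]; q.push(w); }
    }
  }
  return out;
}

// Count exposed 6-neighbour faces of each label that touch a reference mask.
// For every voxel carrying label L, a face towards a 6-neighbour that is NOT
// label L contributes 1 to L's surface count if the neighbour is TRUE in
// `ref`. Used for interaction-surface measurement.
// [[Rcpp::export]]
NumericVector face_contact_counts(IntegerVector labels, LogicalVector ref,
                                  IntegerVector dim, int nlabels) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  NumericVector out(nlabels, 0.0);
  const int dy[6] = {1, -1, 0, 0, 0, 0};
  const int dx[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t v = 0; v < n; ++v) {
    int lab = labels[v];
    if (lab <= 0 || lab > nlabels) continue;
    int y = (int)(v % ny);
    int x = (int)((v / ny) % nx);
    int z = (int)(v / ((R_xlen_t)ny * nx));
    for (int k = 0; k < 6; ++k) {
      int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz) continue;
      R_xlen_t w = yy + (R_xlen_t)ny * xx + (R_xlen_t)ny * nx * zz;
      if (labels[w] != lab && ref[w]) out[lab - 1] += 1.0;
    }
  }
  return out;
}
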