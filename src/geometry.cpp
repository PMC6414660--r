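// Low-level volumetric primitives used by the grids and phantom modules:
// trilinear resampling, separable Gaussian smoothing, binary morphology with
// a cubic structuring element, 26-connected component labelling, and 2D
// signed distance fields (for shape-based inter-slice ROI interpolation).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector values, IntegerVector in_dim,
                                     NumericVector in_spacing, NumericVector in_origin,
                                     IntegerVector out_dim, NumericVector out_spacing,
                                     NumericVector out_origin, double fill) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int mx = out_dim[0], my = out_dim[1], mz = out_dim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double *v = values.begin();
  double *o = out.begin();
  for (int zo = 0; zo < mz; ++zo) {
    const double wz = out_origin[2] + zo * out_spacing[2];
    const double cz = (wz - in_origin[2]) / in_spacing[2];
    for (int yo = 0; yo < my; ++yo) {
      const double wy = out_origin[1] + yo * out_spacing[1];
      const double cy = (wy - in_origin[1]) / in_spacing[1];
      for (int xo = 0; xo < mx; ++xo) {
        const double wx = out_origin[0] + xo * out_spacing[0];
        const double cx = (wx - in_origin[0]) / in_spacing[0];
        double val = fill;
        if (cx >= 0 && cx <= nx - 1 && cy >= 0 && cy <= ny - 1 && cz >= 0 && cz <= nz - 1) {
          int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy), z0 = (int)std::floor(cz);
          if (x0 == nx - 1) x0--; if (y0 == ny - 1) y0--; if (z0 == nz - 1) z0--;
          if (nx == 1) x0 = 0; if (ny == 1) y0 = 0; if (nz == 1) z0 = 0;
          const double fx = nx == 1 ? 0.0 : cx - x0;
          const double fy = ny == 1 ? 0.0 : cy - y0;
          const double fz = nz == 1 ? 0.0 : cz - z0;
          const int x1 = nx == 1 ? x0 : x0 + 1;
          const int y1 = ny == 1 ? y0 : y0 + 1;
          const int z1 = nz == 1 ? z0 : z0 + 1;
          const double c000 = v[vidx(x0, y0, z0, nx, ny)], c100 = v[vidx(x1, y0, z0, nx, ny)];
          const double c010 = v[vidx(x0, y1, z0, nx, ny)], c110 = v[vidx(x1, y1, z0, nx, ny)];
          const double c001 = v[vidx(x0, y0, z1, nx, ny)], c101 = v[vidx(x1, y0, z1, nx, ny)];
          const double c011 = v[vidx(x0, y1, z1, nx, ny)], c111 = v[vidx(x1, y1, z1, nx, ny)];
          const double c00 = c000 * (1 - fx) + c100 * fx;
          const double c10 = c010 * (1 - fx) + c110 * fx;
          const double c01 = c001 * (1 - fx) + c101 * fx;
          const double c11 = c011 * (1 - fx) + c111 * fx;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          val = c0 * (1 - fz) + c1 * fz;
        }
        o[vidx(xo, yo, zo, mx, my)] = val;
      }
    }
  }
  return out;
}

// Separable Gaussian, zero padding, kernel truncated at 3 sigma.
static void smooth_axis(std::vector<double> &v, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &w : k) w /= s;
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  std::vector<double> line(na);
  // iterate over all lines along `axis`
  const int b1 = axis == 0 ? ny : nx;
  const int b2 = axis == 2 ? ny : nz;
  const R_xlen_t s1 = axis == 0 ? stride[1] : stride[0];
  const R_xlen_t s2 = axis == 2 ? stride[1] : stride[2];
  for (int j2 = 0; j2 < b2; ++j2) {
    for (int j1 = 0; j1 < b1; ++j1) {
      const R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; ++i) line[i] = v[base + i * sa];
      for (int i = 0; i < na; ++i) {
        double acc = 0;
        const int lo = std::max(0, i - r), hi = std::min(na - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += line[j] * k[j - i + r];
        v[base + i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3(NumericVector values, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(values.begin(), values.end());
  smooth_axis(v, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(v, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(v, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(values.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// Sliding max (dilate=true) or min along one axis, window radius r.
static void morph_axis(std::vector<int> &v, int nx, int ny, int nz,
                       int axis, int r, bool dilate) {
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  const int b1 = axis == 0 ? ny : nx;
  const int b2 = axis == 2 ? ny : nz;
  const R_xlen_t s1 = axis == 0 ? stride[1] : stride[0];
  const R_xlen_t s2 = axis == 2 ? stride[1] : stride[2];
  std::vector<int> line(na);
  for (int j2 = 0; j2 < b2; ++j2) {
    for (int j1 = 0; j1 < b1; ++j1) {
      const R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; ++i) line[i] = v[base + i * sa];
      for (int i = 0; i < na; ++i) {
        int acc = dilate ? 0 : 1;
        const int lo = std::max(0, i - r), hi = std::min(na - 1, i + r);
        for (int j = lo; j <= hi; ++j) {
          if (dilate) { if (line[j]) { acc = 1; break; } }
          else        { if (!line[j]) { acc = 0; break; } }
        }
        // outside-image voxels count as background: erosion at borders removes
        if (!dilate && (i - r < 0 || i + r > na - 1)) acc = 0;
        v[base + i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerVector dim, int radius,
                               bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> v(mask.begin(), mask.end());
  if (radius > 0)
    for (int a = 0; a < 3; ++a) morph_axis(v, nx, ny, nz, a, radius, dilate);
  IntegerVector out(mask.size());
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// 26-connected component labelling; labels 1..k in decreasing component size.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<R_xlen_t> sizes;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    R_xlen_t sz = 0;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      ++sz;
      const int x = (int)(cur % nx);
      const int y = (int)((cur / nx) % ny);
      const int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            const R_xlen_t q = vidx(xx, yy, zz, nx, ny);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
    sizes.push_back(sz);
  }
  // relabel by decreasing size
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> remap(next + 1, 0);
  for (int rank = 0; rank < next; ++rank) remap[order[rank] + 1] = rank + 1;
  for (R_xlen_t s = 0; s < n; ++s) lab[s] = remap[lab[s]];
  return lab;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= zb[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

static void edt2_sq(const std::vector<char> &m, std::vector<double> &out, int nx, int ny) {
  const double INF = 1e20;
  std::vector<double> f(std::max(nx, ny)), d(std::max(nx, ny));
  out.assign((size_t)nx * ny, 0.0);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      out[(size_t)x + (size_t)nx * y] = m[(size_t)x + (size_t)nx * y] ? 0.0 : INF;
  for (int x = 0; x < nx; ++x) {  // columns (along y)
    for (int y = 0; y < ny; ++y) f[y] = out[(size_t)x + (size_t)nx * y];
    dt1d(f, d, ny);
    for (int y = 0; y < ny; ++y) out[(size_t)x + (size_t)nx * y] = d[y];
  }
  for (int y = 0; y < ny; ++y) {  // rows (along x)
    for (int x = 0; x < nx; ++x) f[x] = out[(size_t)x + (size_t)nx * y];
    dt1d(f, d, nx);
    for (int x = 0; x < nx; ++x) out[(size_t)x + (size_t)nx * y] = d[x];
  }
}

// Signed distance (in voxels) of a 2D mask: negative inside, positive outside.
// [[Rcpp::export]]
NumericVector cpp_sdf2(LogicalVector mask, int nx, int ny) {
  std::vector<char> m((size_t)nx * ny), inv((size_t)nx * ny);
  bool any = false, all = true;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    m[i] = mask[i] != 0;
    inv[i] = !m[i];
    any = any || m[i];
    all = all && m[i];
  }
  NumericVector out((R_xlen_t)nx * ny);
  if (!any) { std::fill(out.begin(), out.end(), 1e6); return out; }
  if (all)  { std::fill(out.begin(), out.end(), -1e6); return out; }
  std::vector<double> dout, din;
  edt2_sq(m, dout, nx, ny);   // distance to nearest foreground (0 inside)
  edt2_sq(inv, din, nx, ny);  // distance to nearest background (0 outside)
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = std::sqrt(dout[i]) - std::sqrt(din[i]);
  return out;
}
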