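#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 26- or 6-connected component labeling of a 3D logical array.
// Returns an integer array of the same shape; 0 = background, components
// numbered 1..k in order of first (column-major) encounter.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims, int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const size_t nnb = dxs.size();

  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t j = 0; j < nnb; ++j) {
        int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !lab[w]) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Fill interior cavities of a 3D mask: background voxels not 6-connected to
// the array border become foreground.
// [[Rcpp::export(name = ".fill_holes3d")]]
LogicalVector fill_holes3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1) continue;
        R_xlen_t v = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
      }

  const int dx6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dz6[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int x = (int)(v % nx);
    int y = (int)((v / nx) % ny);
    int z = (int)(v / ((R_xlen_t)nx * ny));
    for (int j = 0; j < 6; ++j) {
      int xx = x + dx6[j], yy = y + dy6[j], zz = z + dz6[j];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
    }
  }

  LogicalVector out(n);
  out.attr("dim") = dims;
  for (R_xlen_t v = 0; v < n; ++v) out[v] = mask[v] || !outside[v];
  return out;
}

// Separable Gaussian blur of a 3D array; sigma given in voxels per axis,
// kernel truncated at 3 sigma, edges replicated.
// [[Rcpp::export(name = ".blur_gauss3d")]]
NumericVector blur_gauss3d(NumericVector img, IntegerVector dims, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += k[i + r]; }
    for (double &v : k) v /= ksum;

    int len = (ax == 0) ? nx : (ax == 1) ? ny : nz;
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? nx : (R_xlen_t)nx * ny;
    // iterate over all 1D lines along the axis
    for (int z = 0; z < (ax == 2 ? 1 : nz); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y)
        for (int x = 0; x < (ax == 0 ? 1 : nx); ++x) {
          R_xlen_t base = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          for (int i = 0; i < len; ++i) {
            double acc = 0;
            for (int j = -r; j <= r; ++j) {
              int ii = i + j;
              if (ii < 0) ii = 0;
              if (ii >= len) ii = len - 1;
              acc += k[j + r] * a[base + (R_xlen_t)ii * stride];
            }
            b[base + (R_xlen_t)i * stride] = acc;
          }
        }
    std::swap(a, b);
  }

  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}
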