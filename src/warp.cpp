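#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Trilinear / nearest sampling with border (edge-replicate) padding.
// Coordinates are 0-based voxel indices in the source grid.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double samp_linear(const double* v, int nx, int ny, int nz,
                                 double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  #define V(i, j, k) v[(size_t)(i) * sx + (size_t)(j) * sy + (size_t)(k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double samp_nearest(const double* v, int nx, int ny, int nz,
                                  double x, double y, double z) {
  int xi = (int)std::lround(clampd(x, 0.0, nx - 1.0));
  int yi = (int)std::lround(clampd(y, 0.0, ny - 1.0));
  int zi = (int)std::lround(clampd(z, 0.0, nz - 1.0));
  return v[(size_t)xi + (size_t)nx * yi + (size_t)nx * ny * zi];
}

// Resample a 3D volume through an affine map: source_coord = A %*% out_coord + t
// (all coordinates 0-based voxel indices).
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector out_dim,
                                  NumericMatrix A, NumericVector t, bool nearest) {
  IntegerVector d = vol.attr("dim");
  if (d.size() != 3) stop("volume must be a 3D array");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* v = vol.begin();
  double* o = out.begin();
  const double a11 = A(0,0), a12 = A(0,1), a13 = A(0,2);
  const double a21 = A(1,0), a22 = A(1,1), a23 = A(1,2);
  const double a31 = A(2,0), a32 = A(2,1), a33 = A(2,2);
  size_t idx = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++idx) {
        double sx = a11 * i + a12 * j + a13 * k + t[0];
        double sy = a21 * i + a22 * j + a23 * k + t[1];
        double sz = a31 * i + a32 * j + a33 * k + t[2];
        o[idx] = nearest ? samp_nearest(v, nx, ny, nz, sx, sy, sz)
                         : samp_linear(v, nx, ny, nz, sx, sy, sz);
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Warp a volume by a dense displacement field: sample at (x + dx, y + dy, z + dz).
// [[Rcpp::export]]
NumericVector cpp_warp_displacement(NumericVector vol, NumericVector dx,
                                    NumericVector dy, NumericVector dz, bool nearest) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  if (dx.size() != vol.size() || dy.size() != vol.size() || dz.size() != vol.size())
    stop("displacement fields must match the volume's dimensions");
  NumericVector out(vol.size());
  const double* v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double sx = i + dx[idx], sy = j + dy[idx], sz = k + dz[idx];
        out[idx] = nearest ? samp_nearest(v, nx, ny, nz, sx, sy, sz)
                           : samp_linear(v, nx, ny, nz, sx, sy, sz);
      }
  out.attr("dim") = d;
  return out;
}

// Largest 6-connected component of (vol == label): returns a logical mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component6(IntegerVector vol, int label) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> comp(n, 0);
  int ncomp = 0, best = 0;
  size_t best_size = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (vol[s] != label || comp[s] != 0) continue;
    ++ncomp;
    size_t size = 0;
    stack.clear();
    stack.push_back(s);
    comp[s] = ncomp;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      ++size;
      int x = v % nx, y = (v / nx) % ny, z = v / ((size_t)nx * ny);
      const int dx[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        size_t w = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (vol[w] == label && comp[w] == 0) { comp[w] = ncomp; stack.push_back(w); }
      }
    }
    if (size > best_size) { best_size = size; best = ncomp; }
  }
  LogicalVector out(n);
  for (size_t s = 0; s < n; ++s) out[s] = comp[s] == best && best > 0;
  out.attr("dim") = d;
  return out;
}

// Separable Gaussian smoothing with edge-replicate boundary handling.
// sigma is per-axis in voxels; an axis with sigma <= 0 is left untouched.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, NumericVector sigma) {
  IntegerVector d = vol.attr("dim");
  int n[3] = {d[0], d[1], d[2]};
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> tmp(buf.size());
  const size_t stride[3] = {1, (size_t)n[0], (size_t)n[0] * n[1]};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0 || n[ax] == 1) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { kern[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += kern[i + r]; }
    for (auto& k : kern) k /= ksum;
    // iterate over all lines along axis `ax`
    int na = n[ax];
    int ob1 = (ax == 0) ? 1 : 0;           // other axes
    int ob2 = (ax == 2) ? 1 : 2;
    for (int j2 = 0; j2 < n[ob2]; ++j2)
      for (int j1 = 0; j1 < n[ob1]; ++j1) {
        size_t base = stride[ob1] * j1 + stride[ob2] * j2;
        for (int i = 0; i < na; ++i) {
          double acc = 0;
          for (int k = -r; k <= r; ++k) {
            int ii = i + k;
            if (ii < 0) ii = 0; else if (ii >= na) ii = na - 1;
            acc += kern[k + r] * buf[base + stride[ax] * ii];
          }
          tmp[base + stride[ax] * i] = acc;
        }
      }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = d;
  return out;
}
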