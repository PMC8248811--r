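// Low-level 3D image primitives used across the package: separable box sums,
// Gaussian smoothing, trilinear interpolation, real even-order spherical
// harmonic evaluation, per-voxel polar decomposition + ODF reorientation and
// 26/6-connected component labelling. All grids are indexed 0-based, column
// major (x fastest), matching R array layout.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Separable sum over the cubic (2r+1)^3 neighbourhood, truncated at the
// grid border (no padding): exact on integer inputs.
// [[Rcpp::export]]
NumericVector cpp_box_sum(NumericVector img, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double run = 0.0;
      for (int i = 0; i < std::min(radius, nx - 1) + 1; ++i)
        run += a[idx3(i, j, k, nx, ny)];
      for (int i = 0; i < nx; ++i) {
        b[idx3(i, j, k, nx, ny)] = run;
        int add = i + radius + 1, rem = i - radius;
        if (add < nx) run += a[idx3(add, j, k, nx, ny)];
        if (rem >= 0) run -= a[idx3(rem, j, k, nx, ny)];
      }
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      double run = 0.0;
      for (int j = 0; j < std::min(radius, ny - 1) + 1; ++j)
        run += b[idx3(i, j, k, nx, ny)];
      for (int j = 0; j < ny; ++j) {
        a[idx3(i, j, k, nx, ny)] = run;
        int add = j + radius + 1, rem = j - radius;
        if (add < ny) run += b[idx3(i, add, k, nx, ny)];
        if (rem >= 0) run -= b[idx3(i, rem, k, nx, ny)];
      }
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double run = 0.0;
      for (int k = 0; k < std::min(radius, nz - 1) + 1; ++k)
        run += a[idx3(i, j, k, nx, ny)];
      for (int k = 0; k < nz; ++k) {
        b[idx3(i, j, k, nx, ny)] = run;
        int add = k + radius + 1, rem = k - radius;
        if (add < nz) run += a[idx3(i, j, add, nx, ny)];
        if (rem >= 0) run -= a[idx3(i, j, rem, nx, ny)];
      }
    }
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 3 sigma and renormalised
// over the in-bounds support at each voxel (border-preserving).
static void gauss_1d(std::vector<double> &src, std::vector<double> &dst,
                     int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  for (int t = -r; t <= r; ++t)
    ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  int nax = axis == 0 ? nx : (axis == 1 ? ny : nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = axis == 0 ? i : (axis == 1 ? j : k);
        double s = 0.0, wsum = 0.0;
        int lo = std::max(-r, -c), hi = std::min(r, nax - 1 - c);
        for (int t = lo; t <= hi; ++t) {
          int ii = i + (axis == 0 ? t : 0);
          int jj = j + (axis == 1 ? t : 0);
          int kk = k + (axis == 2 ? t : 0);
          s += ker[t + r] * src[idx3(ii, jj, kk, nx, ny)];
          wsum += ker[t + r];
        }
        dst[idx3(i, j, k, nx, ny)] = s / wsum;
      }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector img, IntegerVector dim,
                               double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(img.begin(), img.end()), b(n);
  gauss_1d(a, b, nx, ny, nz, 0, sigma);
  gauss_1d(b, a, nx, ny, nz, 1, sigma);
  gauss_1d(a, b, nx, ny, nz, 2, sigma);
  NumericVector out(n);
  std::copy(b.begin(), b.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Trilinear interpolation of a multi-volume image at 0-based voxel
// coordinates; coordinates are clamped to the grid (replicate border).
// vol: nx*ny*nz*nc vector, coords: m x 3 matrix. Returns m x nc.
// [[Rcpp::export]]
NumericMatrix cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericMatrix coords) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nc = dim.size() > 3 ? dim[3] : 1;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int m = coords.nrow();
  NumericMatrix out(m, nc);
  for (int p = 0; p < m; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
    int i0 = std::min((int)std::floor(x), nx - 2 >= 0 ? nx - 2 : 0);
    int j0 = std::min((int)std::floor(y), ny - 2 >= 0 ? ny - 2 : 0);
    int k0 = std::min((int)std::floor(z), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz),
           w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz),
           w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz,
           w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
    for (int c = 0; c < nc; ++c) {
      const double *v = REAL(vol) + (R_xlen_t)c * nvox;
      out(p, c) = w000 * v[idx3(i0, j0, k0, nx, ny)] +
                  w100 * v[idx3(i1, j0, k0, nx, ny)] +
                  w010 * v[idx3(i0, j1, k0, nx, ny)] +
                  w110 * v[idx3(i1, j1, k0, nx, ny)] +
                  w001 * v[idx3(i0, j0, k1, nx, ny)] +
                  w101 * v[idx3(i1, j0, k1, nx, ny)] +
                  w011 * v[idx3(i0, j1, k1, nx, ny)] +
                  w111 * v[idx3(i1, j1, k1, nx, ny)];
    }
  }
  return out;
}

// Real even-order spherical harmonics. Convention (documented in R/sh.R):
// fully normalised (orthonormal under the uniform spherical measure), no
// Condon-Shortley phase, coefficient order (l, m) lexicographic over even l
// ascending, m = -l..l; column index of (l, m) is l(l-1)/2 + l + m (0-based).
static void sh_row(double ux, double uy, double uz, int lmax, double *row) {
  double ct = uz;                       // cos(theta)
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = std::atan2(uy, ux);
  int Lh = lmax / 2;
  (void)Lh;
  // associated Legendre P_l^m(ct) without Condon-Shortley, l = 0..lmax
  int np = (lmax + 1) * (lmax + 2) / 2;
  std::vector<double> P(np, 0.0);
  auto pidx = [](int l, int m) { return l * (l + 1) / 2 + m; };
  P[pidx(0, 0)] = 1.0;
  for (int m = 1; m <= lmax; ++m)
    P[pidx(m, m)] = (2.0 * m - 1.0) * st * P[pidx(m - 1, m - 1)];
  for (int m = 0; m < lmax; ++m)
    P[pidx(m + 1, m)] = (2.0 * m + 1.0) * ct * P[pidx(m, m)];
  for (int l = 2; l <= lmax; ++l)
    for (int m = 0; m <= l - 2; ++m)
      P[pidx(l, m)] = ((2.0 * l - 1.0) * ct * P[pidx(l - 1, m)] -
                       (l - 1.0 + m) * P[pidx(l - 2, m)]) / (double)(l - m);
  const double fourpi = 4.0 * M_PI;
  for (int l = 0; l <= lmax; l += 2) {
    int off = l * (l - 1) / 2 + l;      // column of (l, 0)
    for (int m = 0; m <= l; ++m) {
      double lg = std::lgamma(l - m + 1.0) - std::lgamma(l + m + 1.0);
      double nrm = std::sqrt((2.0 * l + 1.0) / fourpi * std::exp(lg));
      double plm = P[pidx(l, m)];
      if (m == 0) {
        row[off] = nrm * plm;
      } else {
        double v = M_SQRT2 * nrm * plm;
        row[off + m] = v * std::cos(m * phi);
        row[off - m] = v * std::sin(m * phi);
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sh_basis(NumericMatrix dirs, int lmax) {
  const int n = dirs.nrow();
  const int nc = (lmax + 1) * (lmax + 2) / 2;
  NumericMatrix out(n, nc);
  std::vector<double> row(nc);
  for (int i = 0; i < n; ++i) {
    sh_row(dirs(i, 0), dirs(i, 1), dirs(i, 2), lmax, row.data());
    for (int c = 0; c < nc; ++c) out(i, c) = row[c];
  }
  return out;
}

// Rotation factor of the polar decomposition J = R S for a batch of 3x3
// matrices (rows: j11 j21 j31 j12 j22 j32 j13 j23 j33, column-major per
// matrix). Reflections are repaired to proper rotations.
// [[Rcpp::export]]
NumericMatrix cpp_polar_rotations(NumericMatrix jac) {
  const int n = jac.nrow();
  NumericMatrix out(n, 9);
  arma::mat33 J, U, V, R;
  arma::vec3 s;
  for (int p = 0; p < n; ++p) {
    for (int c = 0; c < 9; ++c) J(c % 3, c / 3) = jac(p, c);
    bool ok = arma::svd(U, s, V, J, "std");
    if (!ok) { R.eye(); }
    else {
      R = U * V.t();
      if (arma::det(R) < 0) {          // flip the weakest direction
        U.col(2) *= -1.0;
        R = U * V.t();
      }
    }
    for (int c = 0; c < 9; ++c) out(p, c) = R(c % 3, c / 3);
  }
  return out;
}

// Apply per-voxel rotations to SH coefficient vectors by the
// evaluate-rotate-refit construction: sample the rotated function f(R^T d)
// on a quadrature direction set and project back with P = B' diag(w).
// coeffs: n x ncoef, rot: n x 9 (column-major 3x3), dirs: q x 3,
// proj: ncoef x q. Returns n x ncoef.
// [[Rcpp::export]]
NumericMatrix cpp_sh_reorient(NumericMatrix coeffs, NumericMatrix rot,
                              int lmax, NumericMatrix dirs,
                              NumericMatrix proj) {
  const int n = coeffs.nrow(), nc = coeffs.ncol(), q = dirs.nrow();
  NumericMatrix out(n, nc);
  std::vector<double> row(nc), samp(q);
  for (int p = 0; p < n; ++p) {
    // skip voxels with no SH content
    double ss = 0.0;
    for (int c = 0; c < nc; ++c) ss += coeffs(p, c) * coeffs(p, c);
    if (ss == 0.0) continue;
    double R[9];
    for (int c = 0; c < 9; ++c) R[c] = rot(p, c);
    for (int j = 0; j < q; ++j) {
      // d' = R^T d  (rotated function evaluated at quadrature node d)
      double dx = dirs(j, 0), dy = dirs(j, 1), dz = dirs(j, 2);
      double ux = R[0] * dx + R[1] * dy + R[2] * dz;
      double uy = R[3] * dx + R[4] * dy + R[5] * dz;
      double uz = R[6] * dx + R[7] * dy + R[8] * dz;
      sh_row(ux, uy, uz, lmax, row.data());
      double s = 0.0;
      for (int c = 0; c < nc; ++c) s += row[c] * coeffs(p, c);
      samp[j] = s;
    }
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int j = 0; j < q; ++j) s += proj(c, j) * samp[j];
      out(p, c) = s;
    }
  }
  return out;
}

// Connected components of a binary mask (6 or 26 connectivity), BFS.
// Labels are assigned in scan order; relabelling by size happens in R.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;
  std::vector<std::array<int, 3>> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({di, dj, dk});
      }
  int next = 0;
  std::queue<std::array<int, 3>> qu;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = idx3(i, j, k, nx, ny);
        if (mask[v] == 0 || lab[v] != 0) continue;
        lab[v] = ++next;
        qu.push({i, j, k});
        while (!qu.empty()) {
          auto cur = qu.front(); qu.pop();
          for (auto &d : nb) {
            int ii = cur[0] + d[0], jj = cur[1] + d[1], kk = cur[2] + d[2];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = next;
              qu.push({ii, jj, kk});
            }
          }
        }
      }
  return lab;
}
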