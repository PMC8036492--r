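// Low-level numerical kernels: 3D interpolation, morphology, separable
// Gaussian filtering, and the valid-convolution stack (im2col + GEMM)
// used by the voxel-classification network.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Keys cubic convolution kernel, a = -0.5 (interpolating: weights sum to 1)
static inline double keys_w(double t) {
  t = std::fabs(t);
  if (t < 1.0) return ((1.5 * t - 2.5) * t) * t + 1.0;
  if (t < 2.0) return ((-0.5 * t + 2.5) * t - 4.0) * t + 2.0;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Interpolate a 3D array at continuous 0-based voxel coordinates.
// order: 0 nearest, 1 trilinear, 3 cubic (Keys). Coordinates outside the
// array domain return `fill`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector arr, IntegerVector dim,
                          NumericMatrix coords, int order, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double* a = REAL(arr);
  const double* cx = &coords(0, 0);
  const double* cy = &coords(0, 1);
  const double* cz = &coords(0, 2);
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;

  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = cx[p], y = cy[p], z = cz[p];
    if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
        x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    if (order == 0) {
      int i = clampi((int)std::lround(x), 0, nx - 1);
      int j = clampi((int)std::lround(y), 0, ny - 1);
      int k = clampi((int)std::lround(z), 0, nz - 1);
      out[p] = a[i * sx + j * sy + k * sz];
    } else if (order == 1) {
      int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
      if (i >= nx - 1) i = nx > 1 ? nx - 2 : 0;
      if (j >= ny - 1) j = ny > 1 ? ny - 2 : 0;
      if (k >= nz - 1) k = nz > 1 ? nz - 2 : 0;
      const double fx = x - i, fy = y - j, fz = z - k;
      const int i1 = nx > 1 ? i + 1 : i, j1 = ny > 1 ? j + 1 : j,
                k1 = nz > 1 ? k + 1 : k;
      const double c000 = a[i * sx + j * sy + k * sz];
      const double c100 = a[i1 * sx + j * sy + k * sz];
      const double c010 = a[i * sx + j1 * sy + k * sz];
      const double c110 = a[i1 * sx + j1 * sy + k * sz];
      const double c001 = a[i * sx + j * sy + k1 * sz];
      const double c101 = a[i1 * sx + j * sy + k1 * sz];
      const double c011 = a[i * sx + j1 * sy + k1 * sz];
      const double c111 = a[i1 * sx + j1 * sy + k1 * sz];
      out[p] =
        (1 - fz) * ((1 - fy) * ((1 - fx) * c000 + fx * c100) +
                    fy * ((1 - fx) * c010 + fx * c110)) +
        fz * ((1 - fy) * ((1 - fx) * c001 + fx * c101) +
              fy * ((1 - fx) * c011 + fx * c111));
    } else {
      // cubic: 4x4x4 neighbourhood with edge clamping
      const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
                k0 = (int)std::floor(z);
      double wx[4], wy[4], wz[4];
      int ix[4], jy[4], kz[4];
      for (int m = 0; m < 4; ++m) {
        const int off = m - 1;
        wx[m] = keys_w(x - (i0 + off));
        wy[m] = keys_w(y - (j0 + off));
        wz[m] = keys_w(z - (k0 + off));
        ix[m] = clampi(i0 + off, 0, nx - 1);
        jy[m] = clampi(j0 + off, 0, ny - 1);
        kz[m] = clampi(k0 + off, 0, nz - 1);
      }
      double acc = 0.0;
      for (int mk = 0; mk < 4; ++mk) {
        if (wz[mk] == 0.0) continue;
        for (int mj = 0; mj < 4; ++mj) {
          const double wzy = wz[mk] * wy[mj];
          if (wzy == 0.0) continue;
          const size_t base = jy[mj] * sy + kz[mk] * sz;
          for (int mi = 0; mi < 4; ++mi)
            acc += wzy * wx[mi] * a[ix[mi] * sx + base];
        }
      }
      out[p] = acc;
    }
  }
  return out;
}

// derivative of the Keys kernel
static inline double keys_dw(double x) {
  const double s = x < 0 ? -1.0 : 1.0;
  const double t = std::fabs(x);
  if (t < 1.0) return s * (4.5 * t - 5.0) * t;
  if (t < 2.0) return s * ((-1.5 * t + 5.0) * t - 4.0);
  return 0.0;
}

// Interpolation with the exact partial derivatives of the interpolant
// w.r.t. the continuous voxel coordinates; returns an n x 4 matrix
// (value, d/dx, d/dy, d/dz). order 1 (trilinear, piecewise C0) or 3
// (Keys cubic, C1 — preferred for gradient-based optimisation).
// Out-of-domain points: fill, zero gradient.
// [[Rcpp::export]]
NumericMatrix cpp_interp3_grad(NumericVector arr, IntegerVector dim,
                               NumericMatrix coords, double fill,
                               int order = 1) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericMatrix out(n, 4);
  const double* a = REAL(arr);
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  if (order == 3) {
    for (R_xlen_t p = 0; p < n; ++p) {
      const double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
      if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
          x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out(p, 0) = fill;
        continue;
      }
      const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
                k0 = (int)std::floor(z);
      double wx[4], wy[4], wz[4], dx[4], dy[4], dz[4];
      int ix[4], jy[4], kz[4];
      for (int m = 0; m < 4; ++m) {
        const int off = m - 1;
        wx[m] = keys_w(x - (i0 + off));  dx[m] = keys_dw(x - (i0 + off));
        wy[m] = keys_w(y - (j0 + off));  dy[m] = keys_dw(y - (j0 + off));
        wz[m] = keys_w(z - (k0 + off));  dz[m] = keys_dw(z - (k0 + off));
        ix[m] = clampi(i0 + off, 0, nx - 1);
        jy[m] = clampi(j0 + off, 0, ny - 1);
        kz[m] = clampi(k0 + off, 0, nz - 1);
      }
      double v = 0, gx = 0, gy = 0, gz = 0;
      for (int mk = 0; mk < 4; ++mk)
        for (int mj = 0; mj < 4; ++mj) {
          const size_t base = jy[mj] * sy + kz[mk] * sz;
          for (int mi = 0; mi < 4; ++mi) {
            const double c = a[ix[mi] * sx + base];
            v  += wz[mk] * wy[mj] * wx[mi] * c;
            gx += wz[mk] * wy[mj] * dx[mi] * c;
            gy += wz[mk] * dy[mj] * wx[mi] * c;
            gz += dz[mk] * wy[mj] * wx[mi] * c;
          }
        }
      out(p, 0) = v; out(p, 1) = gx; out(p, 2) = gy; out(p, 3) = gz;
    }
    return out;
  }
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!(x >= 0.0) || !(y >= 0.0) || !(z >= 0.0) ||
        x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out(p, 0) = fill;
      continue;
    }
    int i = (int)std::floor(x), j = (int)std::floor(y), k = (int)std::floor(z);
    if (i >= nx - 1) i = nx > 1 ? nx - 2 : 0;
    if (j >= ny - 1) j = ny > 1 ? ny - 2 : 0;
    if (k >= nz - 1) k = nz > 1 ? nz - 2 : 0;
    const double fx = x - i, fy = y - j, fz = z - k;
    const int i1 = nx > 1 ? i + 1 : i, j1 = ny > 1 ? j + 1 : j,
              k1 = nz > 1 ? k + 1 : k;
    const double c000 = a[i * sx + j * sy + k * sz];
    const double c100 = a[i1 * sx + j * sy + k * sz];
    const double c010 = a[i * sx + j1 * sy + k * sz];
    const double c110 = a[i1 * sx + j1 * sy + k * sz];
    const double c001 = a[i * sx + j * sy + k1 * sz];
    const double c101 = a[i1 * sx + j * sy + k1 * sz];
    const double c011 = a[i * sx + j1 * sy + k1 * sz];
    const double c111 = a[i1 * sx + j1 * sy + k1 * sz];
    const double c00 = (1 - fx) * c000 + fx * c100;
    const double c10 = (1 - fx) * c010 + fx * c110;
    const double c01 = (1 - fx) * c001 + fx * c101;
    const double c11 = (1 - fx) * c011 + fx * c111;
    const double c0 = (1 - fy) * c00 + fy * c10;
    const double c1 = (1 - fy) * c01 + fy * c11;
    out(p, 0) = (1 - fz) * c0 + fz * c1;
    out(p, 1) = (1 - fz) * ((1 - fy) * (c100 - c000) + fy * (c110 - c010)) +
                fz * ((1 - fy) * (c101 - c001) + fy * (c111 - c011));
    out(p, 2) = (1 - fz) * (c10 - c00) + fz * (c11 - c01);
    out(p, 3) = c1 - c0;
  }
  return out;
}

// Binary dilation by `iters` iterations of the full 3x3x3 (26-connected)
// structuring element, i.e. a Chebyshev ball of radius `iters`.
// [[Rcpp::export]]
IntegerVector cpp_dilate26(IntegerVector mask, IntegerVector dim, int iters) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<int> cur(mask.begin(), mask.end()), nxt(nvox);
  for (int it = 0; it < iters; ++it) {
    for (int k = 0; k < nz; ++k) {
      const int k0 = std::max(0, k - 1), k1 = std::min(nz - 1, k + 1);
      for (int j = 0; j < ny; ++j) {
        const int j0 = std::max(0, j - 1), j1 = std::min(ny - 1, j + 1);
        for (int i = 0; i < nx; ++i) {
          const int i0 = std::max(0, i - 1), i1 = std::min(nx - 1, i + 1);
          int v = 0;
          for (int kk = k0; kk <= k1 && !v; ++kk)
            for (int jj = j0; jj <= j1 && !v; ++jj)
              for (int ii = i0; ii <= i1; ++ii)
                if (cur[ii + (size_t)nx * (jj + (size_t)ny * kk)]) { v = 1; break; }
          nxt[i + (size_t)nx * (j + (size_t)ny * k)] = v;
        }
      }
    }
    cur.swap(nxt);
  }
  return IntegerVector(cur.begin(), cur.end());
}

// Separable Gaussian blur, sigma given in voxels per axis, mirror boundary.
// Kernel truncated at 4 sigma and renormalised.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur3(NumericVector arr, IntegerVector dim,
                              NumericVector sigma) {
  const int nd[3] = { dim[0], dim[1], dim[2] };
  std::vector<double> buf(arr.begin(), arr.end()), tmp(buf.size());
  const size_t strides[3] = { 1, (size_t)nd[0], (size_t)nd[0] * nd[1] };
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> w(2 * r + 1);
    double wsum = 0.0;
    for (int m = -r; m <= r; ++m) {
      w[m + r] = std::exp(-0.5 * (double)m * m / (s * s));
      wsum += w[m + r];
    }
    for (double& v : w) v /= wsum;
    const int n = nd[ax];
    const size_t st = strides[ax];
    const int na = nd[(ax + 1) % 3], nb = nd[(ax + 2) % 3];
    const size_t sa = strides[(ax + 1) % 3], sb = strides[(ax + 2) % 3];
    for (int b = 0; b < nb; ++b)
      for (int a2 = 0; a2 < na; ++a2) {
        const size_t base = (size_t)a2 * sa + (size_t)b * sb;
        for (int i = 0; i < n; ++i) {
          double acc = 0.0;
          for (int m = -r; m <= r; ++m) {
            int q = i + m;
            // mirror about the edge voxels (period 2n-2)
            if (n > 1) {
              while (q < 0 || q > n - 1) {
                if (q < 0) q = -q;
                if (q > n - 1) q = 2 * (n - 1) - q;
              }
            } else q = 0;
            acc += w[m + r] * buf[base + (size_t)q * st];
          }
          tmp[base + (size_t)i * st] = acc;
        }
      }
    buf.swap(tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// ---- convolution stack ------------------------------------------------
// Feature maps are stored as (nvox, channels) matrices, voxel index
// varying fastest in x (R array order). Weights for a k^3 convolution are
// (k^3 * cin, cout) with row index kk + k^3 * c, kk = di + k*(dj + k*dk).

static arma::mat im2col3(const arma::mat& X, int nx, int ny, int nz, int k) {
  const int ox = nx - k + 1, oy = ny - k + 1, oz = nz - k + 1;
  const int cin = X.n_cols, k3 = k * k * k;
  arma::mat C((size_t)ox * oy * oz, (size_t)k3 * cin);
  for (int c = 0; c < cin; ++c) {
    const double* src = X.colptr(c);
    for (int dk = 0; dk < k; ++dk)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int kk = di + k * (dj + k * dk);
          double* dst = C.colptr((size_t)c * k3 + kk);
          size_t idx = 0;
          for (int z = 0; z < oz; ++z)
            for (int y = 0; y < oy; ++y) {
              const double* s =
                src + di + (size_t)nx * ((y + dj) + (size_t)ny * (z + dk));
              std::memcpy(dst + idx, s, sizeof(double) * ox);
              idx += ox;
            }
        }
  }
  return C;
}

static void col2im3_add(arma::mat& X, const arma::mat& dC,
                        int nx, int ny, int nz, int k) {
  const int ox = nx - k + 1, oy = ny - k + 1, oz = nz - k + 1;
  const int cin = X.n_cols, k3 = k * k * k;
  for (int c = 0; c < cin; ++c) {
    double* dst = X.colptr(c);
    for (int dk = 0; dk < k; ++dk)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int kk = di + k * (dj + k * dk);
          const double* src = dC.colptr((size_t)c * k3 + kk);
          size_t idx = 0;
          for (int z = 0; z < oz; ++z)
            for (int y = 0; y < oy; ++y) {
              double* d =
                dst + di + (size_t)nx * ((y + dj) + (size_t)ny * (z + dk));
              for (int x = 0; x < ox; ++x) d[x] += src[idx + x];
              idx += ox;
            }
        }
  }
}

struct LayerIO {
  arma::mat pre;   // pre-activation (or post-dropout activation input to next)
  int nx, ny, nz;
};

// Forward pass; if `target` is provided, also run backward and return
// gradients and the mean cross-entropy loss. Dropout masks (inverted
// dropout, values 0 or 1/keep) are applied after ReLU of the layers they
// are supplied for; pass R_NilValue entries to skip.
// [[Rcpp::export]]
List cpp_net_apply(NumericVector x, IntegerVector dims, List W, List b,
                   IntegerVector kern, List dropmask,
                   Nullable<IntegerVector> target) {
  const int L = W.size();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin0 = dims.size() > 3 ? dims[3] : 1;
  arma::mat A((size_t)nx * ny * nz, cin0);
  std::copy(x.begin(), x.end(), A.memptr());

  const bool backward = target.isNotNull();
  std::vector<arma::mat> acts(L + 1);   // inputs to each layer
  std::vector<arma::mat> cols(L);       // cached im2col matrices
  std::vector<arma::mat> relum(L);      // relu derivative masks (hidden)
  std::vector<int> dx(L + 1), dy(L + 1), dz(L + 1);
  acts[0] = A; dx[0] = nx; dy[0] = ny; dz[0] = nz;

  for (int l = 0; l < L; ++l) {
    const int k = kern[l];
    const arma::mat Wl = as<arma::mat>(W[l]);
    const arma::rowvec bl = as<arma::rowvec>(b[l]);
    arma::mat col = (k == 1) ? acts[l] : im2col3(acts[l], dx[l], dy[l], dz[l], k);
    if (backward && k != 1) cols[l] = col;
    arma::mat Z = col * Wl;
    Z.each_row() += bl;
    dx[l + 1] = dx[l] - k + 1; dy[l + 1] = dy[l] - k + 1; dz[l + 1] = dz[l] - k + 1;
    if (l < L - 1) {
      relum[l] = arma::conv_to<arma::mat>::from(Z > 0.0);
      Z %= relum[l];
      if (dropmask.size() > l && !Rf_isNull(dropmask[l])) {
        arma::vec dm = as<arma::vec>(dropmask[l]);
        Z %= arma::reshape(dm, Z.n_rows, Z.n_cols);
      }
    }
    acts[l + 1] = Z;
  }

  // softmax over classes (last layer, 2+ columns)
  arma::mat& Zf = acts[L];
  arma::mat P = Zf;
  arma::vec mx = arma::max(P, 1);
  P.each_col() -= mx;
  P = arma::exp(P);
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;

  if (target.isNull()) {
    return List::create(_["prob"] = P,
                        _["odim"] = IntegerVector::create(dx[L], dy[L], dz[L]));
  }

  IntegerVector tgt(target);
  const size_t nout = P.n_rows;
  double loss = 0.0;
  arma::mat dZ = P;
  for (size_t i = 0; i < nout; ++i) {
    const int cls = tgt[i];
    loss -= std::log(std::max(P(i, cls), 1e-12));
    dZ(i, cls) -= 1.0;
  }
  loss /= (double)nout;
  dZ /= (double)nout;

  List gW(L), gb(L);
  arma::mat delta = dZ;
  for (int l = L - 1; l >= 0; --l) {
    const int k = kern[l];
    const arma::mat& col = (k == 1) ? acts[l] : cols[l];
    const arma::mat Wl = as<arma::mat>(W[l]);
    gW[l] = wrap(arma::mat(col.t() * delta));
    gb[l] = wrap(arma::rowvec(arma::sum(delta, 0)));
    if (l > 0) {
      arma::mat dcol = delta * Wl.t();
      arma::mat dA;
      if (k == 1) {
        dA = dcol;
      } else {
        dA.zeros(acts[l].n_rows, acts[l].n_cols);
        col2im3_add(dA, dcol, dx[l], dy[l], dz[l], k);
      }
      // back through dropout + relu of layer l-1
      if (dropmask.size() > l - 1 && !Rf_isNull(dropmask[l - 1])) {
        arma::vec dm = as<arma::vec>(dropmask[l - 1]);
        dA %= arma::reshape(dm, dA.n_rows, dA.n_cols);
      }
      dA %= relum[l - 1];
      delta = dA;
    }
  }
  return List::create(_["loss"] = loss, _["gW"] = gW, _["gb"] = gb,
                      _["prob"] = P,
                      _["odim"] = IntegerVector::create(dx[L], dy[L], dz[L]));
}
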