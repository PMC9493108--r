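// Compute kernels: Gaussian rendering/projection of point models,
// central-slice insertion for direct Fourier reconstruction, and
// im2col-based 2D convolution (forward/backward) for the network
// engine.
//
// Conventions shared with the R side:
//  * volumes/images are column-major with x the fastest axis;
//  * the model origin (0,0,0) maps to grid index n/2 (0-based), i.e.
//    the standard FFT center;
//  * Fourier-space cubes passed here are fftshift-ed (DC at n/2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------
// Rendering: sum of normalized isotropic 3D Gaussians on the grid.
// Truncated at 6 sigma; mass-weighted; integral of each Gaussian is
// its mass (so voxel_sum * voxel_volume ~ total mass).

// [[Rcpp::export]]
NumericVector cpp_render_density(const NumericMatrix& coords,
                                 const NumericVector& masses,
                                 double sigma, int size,
                                 double voxel, double ox, double oy,
                                 double oz) {
  NumericVector out(size * (R_xlen_t)size * size);
  out.attr("dim") = IntegerVector::create(size, size, size);
  const double c = size / 2.0;  // grid index of model origin
  const double cut = 6.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / std::pow(2.0 * M_PI * sigma * sigma, 1.5);
  for (int a = 0; a < coords.nrow(); ++a) {
    // grid coordinates of the point
    const double gx = (coords(a, 0) - ox) / voxel + c;
    const double gy = (coords(a, 1) - oy) / voxel + c;
    const double gz = (coords(a, 2) - oz) / voxel + c;
    const double m = masses[a] * norm;
    const int x0 = std::max(0, (int)std::ceil(gx - cut / voxel));
    const int x1 = std::min(size - 1, (int)std::floor(gx + cut / voxel));
    const int y0 = std::max(0, (int)std::ceil(gy - cut / voxel));
    const int y1 = std::min(size - 1, (int)std::floor(gy + cut / voxel));
    const int z0 = std::max(0, (int)std::ceil(gz - cut / voxel));
    const int z1 = std::min(size - 1, (int)std::floor(gz + cut / voxel));
    for (int z = z0; z <= z1; ++z) {
      const double dz = (z - gz) * voxel;
      for (int y = y0; y <= y1; ++y) {
        const double dy = (y - gy) * voxel;
        const double r2yz = dy * dy + dz * dz;
        R_xlen_t base = ((R_xlen_t)z * size + y) * size;
        for (int x = x0; x <= x1; ++x) {
          const double dx = (x - gx) * voxel;
          out[base + x] += m * std::exp(-(dx * dx + r2yz) * inv2s2);
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------
// Projection: exact line integral along z of the 3D Gaussians = 2D
// Gaussians of the same sigma, splatted at the (rotated) xy positions.
// coords2: N x 2 positions in Angstrom (already rotated, shifted).

// [[Rcpp::export]]
NumericMatrix cpp_project_points(const NumericMatrix& coords2,
                                 const NumericVector& masses,
                                 double sigma, int size,
                                 double pixel) {
  NumericMatrix out(size, size);   // [x, y]
  const double c = size / 2.0;
  const double cut = 6.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (2.0 * M_PI * sigma * sigma);
  for (int a = 0; a < coords2.nrow(); ++a) {
    const double gx = coords2(a, 0) / pixel + c;
    const double gy = coords2(a, 1) / pixel + c;
    const double m = masses[a] * norm;
    const int x0 = std::max(0, (int)std::ceil(gx - cut / pixel));
    const int x1 = std::min(size - 1, (int)std::floor(gx + cut / pixel));
    const int y0 = std::max(0, (int)std::ceil(gy - cut / pixel));
    const int y1 = std::min(size - 1, (int)std::floor(gy + cut / pixel));
    for (int y = y0; y <= y1; ++y) {
      const double dy = (y - gy) * pixel;
      for (int x = x0; x <= x1; ++x) {
        const double dx = (x - gx) * pixel;
        out(x, y) += m * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------
// Direct Fourier inversion: insert each image's centered 2D FFT as a
// central slice oriented by its rotation, with trilinear gridding.
// fimg: (L, L, K) fftshift-ed 2D transforms (shift-corrected).
// rots: (3, 3, K) rotation matrices (model-rotation convention; the
// slice point for 2D frequency k is R^T (kx, ky, 0)).

// [[Rcpp::export]]
List cpp_insert_slices(const arma::cx_cube& fimg,
                       const arma::cube& rots) {
  const int L = fimg.n_rows;
  const int K = fimg.n_slices;
  const int c = L / 2;
  arma::cx_cube num(L, L, L, arma::fill::zeros);
  arma::cube wt(L, L, L, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const arma::mat R = rots.slice(k);
    for (int j = 0; j < L; ++j) {
      const double ky = j - c;
      for (int i = 0; i < L; ++i) {
        const double kx = i - c;
        if (kx * kx + ky * ky > (double)c * c) continue;  // keep sphere
        const std::complex<double> v = fimg(i, j, k);
        // 3D frequency = R^T (kx, ky, 0)
        const double fx = R(0, 0) * kx + R(1, 0) * ky;
        const double fy = R(0, 1) * kx + R(1, 1) * ky;
        const double fz = R(0, 2) * kx + R(1, 2) * ky;
        const double gx = fx + c, gy = fy + c, gz = fz + c;
        const int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy),
                  z0 = (int)std::floor(gz);
        const double ax = gx - x0, ay = gy - y0, az = gz - z0;
        for (int dz = 0; dz <= 1; ++dz) {
          const int z = z0 + dz;
          if (z < 0 || z >= L) continue;
          const double wz = dz ? az : 1 - az;
          for (int dy = 0; dy <= 1; ++dy) {
            const int y = y0 + dy;
            if (y < 0 || y >= L) continue;
            const double wy = dy ? ay : 1 - ay;
            for (int dx = 0; dx <= 1; ++dx) {
              const int x = x0 + dx;
              if (x < 0 || x >= L) continue;
              const double w = wz * wy * (dx ? ax : 1 - ax);
              num(x, y, z) += v * w;
              wt(x, y, z) += w;
            }
          }
        }
      }
    }
  }
  return List::create(Named("numerator") = num,
                      Named("weight") = wt);
}

// ---------------------------------------------------------------------
// CNN convolution via im2col + GEMM.  Layouts (column-major R arrays):
//   x : (H, W, Cin, B)     w : (K, K, Cin, Cout)    y : (Ho, Wo, Cout, B)
// Zero padding `pad`, square kernel, equal stride in both directions.

static void im2col(const double* x, int H, int W, int C,
                   int K, int stride, int pad, int Ho, int Wo,
                   arma::mat& cols, int col_offset) {
  // cols: (C*K*K) x (>= Ho*Wo); fill columns col_offset .. +Ho*Wo-1
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = col_offset + wo * Ho + ho;
      double* dst = cols.colptr(col);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int wi = wo * stride - pad + kw;
          for (int kh = 0; kh < K; ++kh, ++r) {
            const int hi = ho * stride - pad + kh;
            dst[r] = (hi >= 0 && hi < H && wi >= 0 && wi < W)
                       ? xc[(R_xlen_t)wi * H + hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C,
                   int K, int stride, int pad, int Ho, int Wo,
                   double* x, int col_offset) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = col_offset + wo * Ho + ho;
      const double* src = cols.colptr(col);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = x + (R_xlen_t)c * H * W;
        for (int kw = 0; kw < K; ++kw) {
          const int wi = wo * stride - pad + kw;
          for (int kh = 0; kh < K; ++kh, ++r) {
            const int hi = ho * stride - pad + kh;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              xc[(R_xlen_t)wi * H + hi] += src[r];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(const NumericVector& x,
                                 const NumericVector& w,
                                 const NumericVector& bias,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  arma::mat wm(const_cast<double*>(w.begin()), K * K * Cin, Cout,
               false, true);
  arma::mat cols(Cin * K * K, (R_xlen_t)Ho * Wo * B);
  for (int b = 0; b < B; ++b)
    im2col(x.begin() + (R_xlen_t)b * H * W * Cin, H, W, Cin, K,
           stride, pad, Ho, Wo, cols, b * Ho * Wo);
  arma::mat ym = cols.t() * wm;          // (Ho*Wo*B) x Cout
  NumericVector y((R_xlen_t)Ho * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < Cout; ++c) {
      const double bc = bias[c];
      const double* src = ym.colptr(c) + (R_xlen_t)b * Ho * Wo;
      double* dst = yp + ((R_xlen_t)b * Cout + c) * Ho * Wo;
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i)
        dst[i] = src[i] + bc;
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const NumericVector& x,
                         const NumericVector& w,
                         const NumericVector& dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"),
                yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  arma::mat wm(const_cast<double*>(w.begin()), K * K * Cin, Cout,
               false, true);
  // reshape dy into (Ho*Wo*B) x Cout
  arma::mat dym((R_xlen_t)Ho * Wo * B, Cout);
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < Cout; ++c) {
      const double* src = dyp + ((R_xlen_t)b * Cout + c) * Ho * Wo;
      double* dst = dym.colptr(c) + (R_xlen_t)b * Ho * Wo;
      std::copy(src, src + (R_xlen_t)Ho * Wo, dst);
    }
  arma::mat cols(Cin * K * K, (R_xlen_t)Ho * Wo * B);
  for (int b = 0; b < B; ++b)
    im2col(x.begin() + (R_xlen_t)b * H * W * Cin, H, W, Cin, K,
           stride, pad, Ho, Wo, cols, b * Ho * Wo);
  arma::mat dwm = cols * dym;            // (Cin*K*K) x Cout
  arma::mat dcols = wm * dym.t();        // (Cin*K*K) x (Ho*Wo*B)
  NumericVector dx((R_xlen_t)H * W * Cin * B);
  dx.attr("dim") = xd;
  for (int b = 0; b < B; ++b)
    col2im(dcols, H, W, Cin, K, stride, pad, Ho, Wo,
           dx.begin() + (R_xlen_t)b * H * W * Cin, b * Ho * Wo);
  NumericVector dw(w.length());
  dw.attr("dim") = wd;
  std::copy(dwm.begin(), dwm.end(), dw.begin());
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c)
    db[c] = arma::accu(dym.col(c));
  return List::create(Named("dx") = dx, Named("dw") = dw,
                      Named("db") = db);
}

// ---------------------------------------------------------------------
// Batch norm over (H, W, C, B) arrays: per-channel statistics across
// all spatial positions and batch samples, without any transposition.

static inline void bn_dims(const NumericVector& x, int& hw, int& C,
                           int& B) {
  IntegerVector d = x.attr("dim");
  hw = d[0] * d[1];
  C = d[2];
  B = d[3];
}

// [[Rcpp::export]]
List cpp_bn_stats(const NumericVector& x) {
  int hw, C, B;
  bn_dims(x, hw, C, B);
  NumericVector mu(C), va(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + ((R_xlen_t)b * C + c) * hw;
      for (int i = 0; i < hw; ++i) {
        s += p[i];
        s2 += p[i] * p[i];
      }
    }
    const double n = (double)hw * B;
    mu[c] = s / n;
    va[c] = s2 / n - mu[c] * mu[c];
  }
  return List::create(Named("mu") = mu, Named("va") = va);
}

// [[Rcpp::export]]
NumericVector cpp_bn_forward(const NumericVector& x,
                             const NumericVector& gamma,
                             const NumericVector& beta,
                             const NumericVector& mu,
                             const NumericVector& va, double eps) {
  int hw, C, B;
  bn_dims(x, hw, C, B);
  NumericVector y(x.length());
  y.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(va[c] + eps);
    const double a = gamma[c] * inv;
    const double b0 = beta[c] - a * mu[c];
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + ((R_xlen_t)b * C + c) * hw;
      double* q = y.begin() + ((R_xlen_t)b * C + c) * hw;
      for (int i = 0; i < hw; ++i) q[i] = a * p[i] + b0;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_bn_backward(const NumericVector& x, const NumericVector& dy,
                     const NumericVector& gamma,
                     const NumericVector& mu, const NumericVector& va,
                     double eps, bool batch_stats) {
  int hw, C, B;
  bn_dims(x, hw, C, B);
  const double n = (double)hw * B;
  NumericVector dx(x.length()), dgamma(C), dbeta(C);
  dx.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(va[c] + eps);
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const double* px = x.begin() + ((R_xlen_t)b * C + c) * hw;
      const double* pd = dy.begin() + ((R_xlen_t)b * C + c) * hw;
      for (int i = 0; i < hw; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - mu[c]) * inv;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double m_dy = sdy / n, m_dyx = sdyx / n;
    for (int b = 0; b < B; ++b) {
      const double* px = x.begin() + ((R_xlen_t)b * C + c) * hw;
      const double* pd = dy.begin() + ((R_xlen_t)b * C + c) * hw;
      double* q = dx.begin() + ((R_xlen_t)b * C + c) * hw;
      if (batch_stats) {
        for (int i = 0; i < hw; ++i) {
          const double xhat = (px[i] - mu[c]) * inv;
          q[i] = gamma[c] * inv * (pd[i] - m_dy - xhat * m_dyx);
        }
      } else {
        for (int i = 0; i < hw; ++i)
          q[i] = gamma[c] * inv * pd[i];
      }
    }
  }
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(const NumericVector& x) {
  NumericVector y(x.length());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.length(); ++i)
    y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(const NumericVector& y,
                                const NumericVector& dy) {
  NumericVector dx(dy.length());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.length(); ++i)
    dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// Residual add then ReLU, returning the activated sum.
// [[Rcpp::export]]
NumericVector cpp_add_relu(const NumericVector& a,
                           const NumericVector& b) {
  NumericVector y(a.length());
  y.attr("dim") = a.attr("dim");
  for (R_xlen_t i = 0; i < a.length(); ++i) {
    const double s = a[i] + b[i];
    y[i] = s > 0 ? s : 0.0;
  }
  return y;
}

// Forward convolution that also returns the im2col matrix so the
// backward pass can reuse it (saves recomputing the patch gather).
// [[Rcpp::export]]
List cpp_conv2d_forward_cache(const NumericVector& x,
                              const NumericVector& w,
                              const NumericVector& bias,
                              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = (H + 2 * pad - K) / stride + 1;
  const int Wo = (W + 2 * pad - K) / stride + 1;
  arma::mat wm(const_cast<double*>(w.begin()), K * K * Cin, Cout,
               false, true);
  NumericMatrix cols_r(Cin * K * K, Ho * Wo * B);
  arma::mat cols(cols_r.begin(), Cin * K * K, (R_xlen_t)Ho * Wo * B,
                 false, true);
  for (int b = 0; b < B; ++b)
    im2col(x.begin() + (R_xlen_t)b * H * W * Cin, H, W, Cin, K,
           stride, pad, Ho, Wo, cols, b * Ho * Wo);
  arma::mat ym = cols.t() * wm;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  double* yp = y.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < Cout; ++c) {
      const double bc = bias[c];
      const double* src = ym.colptr(c) + (R_xlen_t)b * Ho * Wo;
      double* dst = yp + ((R_xlen_t)b * Cout + c) * Ho * Wo;
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i)
        dst[i] = src[i] + bc;
    }
  return List::create(Named("y") = y, Named("cols") = cols_r);
}

// Backward convolution reusing the cached im2col matrix.
// xdim: c(H, W, Cin, B) of the forward input.
// [[Rcpp::export]]
List cpp_conv2d_backward_cached(const NumericMatrix& cols_r,
                                const NumericVector& w,
                                const NumericVector& dy,
                                const IntegerVector& xdim,
                                int stride, int pad) {
  IntegerVector wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xdim[0], W = xdim[1], Cin = xdim[2], B = xdim[3];
  const int K = wd[0], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  arma::mat wm(const_cast<double*>(w.begin()), K * K * Cin, Cout,
               false, true);
  const arma::mat cols(const_cast<double*>(cols_r.begin()),
                       Cin * K * K, (R_xlen_t)Ho * Wo * B, false,
                       true);
  arma::mat dym((R_xlen_t)Ho * Wo * B, Cout);
  const double* dyp = dy.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < Cout; ++c) {
      const double* src = dyp + ((R_xlen_t)b * Cout + c) * Ho * Wo;
      double* dst = dym.colptr(c) + (R_xlen_t)b * Ho * Wo;
      std::copy(src, src + (R_xlen_t)Ho * Wo, dst);
    }
  arma::mat dwm = cols * dym;
  arma::mat dcols = wm * dym.t();
  NumericVector dx((R_xlen_t)H * W * Cin * B);
  dx.attr("dim") = xdim;
  for (int b = 0; b < B; ++b)
    col2im(dcols, H, W, Cin, K, stride, pad, Ho, Wo,
           dx.begin() + (R_xlen_t)b * H * W * Cin, b * Ho * Wo);
  NumericVector dw(w.length());
  dw.attr("dim") = wd;
  std::copy(dwm.begin(), dwm.end(), dw.begin());
  NumericVector db(Cout);
  for (int c = 0; c < Cout; ++c)
    db[c] = arma::accu(dym.col(c));
  return List::create(Named("dx") = dx, Named("dw") = dw,
                      Named("db") = db);
}

// One fused Adam step for a parameter tensor: returns updated
// parameter, first and second moment in a single pass (with optional
// decoupled-into-gradient L2 weight decay).
// [[Rcpp::export]]
List cpp_adam_step(const NumericVector& p, const NumericVector& g,
                   SEXP m_in, SEXP v_in, double lr, double wd,
                   double beta1, double beta2, double eps, double t) {
  const R_xlen_t n = p.length();
  NumericVector m(n), v(n), out(n);
  out.attr("dim") = p.attr("dim");
  const bool fresh = Rf_isNull(m_in);
  const double* mp = fresh ? nullptr : REAL(m_in);
  const double* vp = fresh ? nullptr : REAL(v_in);
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i] + wd * p[i];
    const double mi = beta1 * (fresh ? 0.0 : mp[i]) + (1 - beta1) * gi;
    const double vi = beta2 * (fresh ? 0.0 : vp[i]) + (1 - beta2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    out[i] = p[i] - lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
  return List::create(Named("p") = out, Named("m") = m,
                      Named("v") = v);
}
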