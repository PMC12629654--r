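// Numerical kernels: 3x3x3 "same" cross-correlation, 2x stride-2 transposed
// convolution, 2x max pooling (all with analytic gradients), grid resampling,
// 26-connected components, and the supersampled thorax phantom renderer.
//
// Feature maps are stored as N x C matrices (column per channel) with voxel
// index  idx = ix + nx*(iy + ny*iz),  matching R's column-major array layout
// for dim = c(nx, ny, nz, C).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::mat Mat;
typedef arma::fmat FMat;

// ---------------------------------------------------------------------------
// 3x3x3 "same" convolution via slab-wise im2col in float32.
//
// The patch matrix S has one column per (offset d, input channel ci) pair,
// column index d * Cin + ci, and one row per voxel of the current z-slab;
// a single SGEMM against the reshaped weight matrix then computes all 27
// offsets at once, which is far more cache-friendly than 27 skinny GEMMs.

// weight matrix (27*Cin x Cout) from the R array laid out c(3,3,3,Cin,Cout)
static FMat conv_weight_matrix(const NumericVector& w, int Cin, int Cout) {
  FMat W(27 * Cin, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 27; ++d)
        W(d * Cin + ci, co) = (float)w[d + 27 * ci + 27 * Cin * co];
  return W;
}

// Fill the patch matrix for slab [z0, z1) in one row-centric pass: for each
// output row the 9*Cin source rows stay cache-resident across all 27
// offsets, and out-of-range entries are written as zeros (so the matrix
// needs no separate zeroing pass).
static void gather_slab(const Mat& x, FMat& S, int Cin, int nx, int ny,
                        int nz, int z0, int z1) {
  for (int iz = z0; iz < z1; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      const R_xlen_t orow = (R_xlen_t)(iz - z0) * nx * ny + (R_xlen_t)iy * nx;
      for (int d = 0; d < 27; ++d) {
        const int sx = d % 3 - 1, sy = (d / 3) % 3 - 1, sz = d / 9 - 1;
        const int jy = iy + sy, jz = iz + sz;
        const bool valid = jy >= 0 && jy < ny && jz >= 0 && jz < nz;
        const int x0 = std::max(0, -sx), x1 = std::min(nx, nx - sx);
        for (int ci = 0; ci < Cin; ++ci) {
          float* dst = S.colptr(d * Cin + ci) + orow;
          if (!valid) { std::memset(dst, 0, nx * sizeof(float)); continue; }
          const double* src =
            x.colptr(ci) + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
          if (sx > 0) dst[nx - 1] = 0.0f;
          if (sx < 0) dst[0] = 0.0f;
          for (int k = x0; k < x1; ++k) dst[k] = (float)src[k + sx];
        }
      }
    }
}

static const int SLAB = 4;  // z-slices per im2col slab

// shared im2col + SGEMM core: out = conv(x) with weight matrix W
// (27*Cin x Cout), optional bias
static Mat conv_core(const Mat& x, int nx, int ny, int nz, const FMat& W,
                     const double* bias) {
  const int Cin = x.n_cols, Cout = W.n_cols;
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  Mat out(N, Cout);
  for (int z0 = 0; z0 < nz; z0 += SLAB) {
    const int z1 = std::min(nz, z0 + SLAB);
    const int rows = nx * ny * (z1 - z0);
    FMat S(rows, 27 * Cin);
    gather_slab(x, S, Cin, nx, ny, nz, z0, z1);
    FMat O = S * W;
    for (int co = 0; co < Cout; ++co) {
      double* oc = out.colptr(co) + (R_xlen_t)nx * ny * z0;
      const float* op = O.colptr(co);
      const double bc = bias ? bias[co] : 0.0;
      for (int i = 0; i < rows; ++i) oc[i] = (double)op[i] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& x, IntegerVector dims,
                         NumericVector w, NumericVector b) {
  const int Cin = x.n_cols, Cout = b.size();
  FMat W = conv_weight_matrix(w, Cin, Cout);
  return conv_core(x, dims[0], dims[1], dims[2], W, b.begin());
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& x, IntegerVector dims, NumericVector w,
                    const arma::mat& gout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = x.n_cols, Cout = gout.n_cols;
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  // Both gradients come from one patch matrix T = im2col(gout):
  //   gx = T * W~   (forward conv of gout with the flipped, transposed kernel)
  //   gW[d,ci,co] = sum_j x[j,ci] * T[j, (26-d)*Cout + co]
  FMat WT(27 * Cout, Cin);
  for (int ci = 0; ci < Cin; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int d = 0; d < 27; ++d)
        WT((26 - d) * Cout + co, ci) = (float)w[d + 27 * ci + 27 * Cin * co];
  Mat gx(N, Cin);
  FMat gWm(Cin, 27 * Cout, arma::fill::zeros);
  for (int z0 = 0; z0 < nz; z0 += SLAB) {
    const int z1 = std::min(nz, z0 + SLAB);
    const int rows = nx * ny * (z1 - z0);
    FMat T(rows, 27 * Cout);
    gather_slab(gout, T, Cout, nx, ny, nz, z0, z1);
    FMat GX = T * WT;
    for (int ci = 0; ci < Cin; ++ci) {
      double* oc = gx.colptr(ci) + (R_xlen_t)nx * ny * z0;
      const float* op = GX.colptr(ci);
      for (int i = 0; i < rows; ++i) oc[i] = (double)op[i];
    }
    FMat Xf(rows, Cin);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = x.colptr(ci) + (R_xlen_t)nx * ny * z0;
      float* xf = Xf.colptr(ci);
      for (int i = 0; i < rows; ++i) xf[i] = (float)xc[i];
    }
    gWm += Xf.t() * T;
  }
  NumericVector gw(w.size());
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 27; ++d)
        gw[d + 27 * ci + 27 * Cin * co] =
          (double)gWm(ci, (26 - d) * Cout + co);
  arma::rowvec gb = arma::sum(gout, 0);
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Transposed convolution, kernel 2x2x2, stride 2 (each output voxel is fed
// by exactly one input voxel).  w layout: dim c(2,2,2,Cin,Cout).  All 8
// offsets are computed in one GEMM against a (Cin x 8*Cout) weight matrix.
static FMat up_weight_matrix(const NumericVector& w, int Cin, int Cout) {
  FMat W(Cin, 8 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 8; ++d)
        W(ci, d * Cout + co) = (float)w[d + 8 * ci + 8 * Cin * co];
  return W;
}

// [[Rcpp::export]]
arma::mat cpp_upconv2_fwd(const arma::mat& x, IntegerVector dims,
                          NumericVector w, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Nin = nx * ny * nz, Cin = x.n_cols, Cout = b.size();
  const int ox = 2 * nx, oy = 2 * ny;
  FMat W = up_weight_matrix(w, Cin, Cout);
  FMat xf = arma::conv_to<FMat>::from(x);
  FMat M = xf * W;                              // Nin x 8*Cout
  Mat out(8 * (R_xlen_t)Nin, Cout);
  for (int d = 0; d < 8; ++d) {
    const int dx = d % 2, dy = (d / 2) % 2, dz = d / 4;
    for (int c = 0; c < Cout; ++c) {
      const float* mc = M.colptr(d * Cout + c);
      double* oc = out.colptr(c);
      const double bc = b[c];
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy) {
          const float* src = mc + nx * (iy + (R_xlen_t)ny * iz);
          double* dst = oc + dx + ox * ((2 * iy + dy) + (R_xlen_t)oy * (2 * iz + dz));
          for (int ixo = 0; ixo < nx; ++ixo) dst[2 * ixo] = (double)src[ixo] + bc;
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_upconv2_bwd(const arma::mat& x, IntegerVector dims, NumericVector w,
                     const arma::mat& gout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Nin = nx * ny * nz, Cin = x.n_cols, Cout = gout.n_cols;
  const int ox = 2 * nx, oy = 2 * ny;
  FMat W = up_weight_matrix(w, Cin, Cout);
  FMat G(Nin, 8 * Cout);
  for (int d = 0; d < 8; ++d) {
    const int dx = d % 2, dy = (d / 2) % 2, dz = d / 4;
    for (int c = 0; c < Cout; ++c) {
      float* sc = G.colptr(d * Cout + c);
      const double* oc = gout.colptr(c);
      for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy) {
          float* dst = sc + nx * (iy + (R_xlen_t)ny * iz);
          const double* src = oc + dx + ox * ((2 * iy + dy) + (R_xlen_t)oy * (2 * iz + dz));
          for (int ixo = 0; ixo < nx; ++ixo) dst[ixo] = (float)src[2 * ixo];
        }
    }
  }
  FMat xf = arma::conv_to<FMat>::from(x);
  FMat gxf = G * W.t();
  FMat gWf = xf.t() * G;
  Mat gx = arma::conv_to<Mat>::from(gxf);
  NumericVector gw(w.size());
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int d = 0; d < 8; ++d)
        gw[d + 8 * ci + 8 * Cin * co] = (double)gWf(ci, d * Cout + co);
  arma::rowvec gb = arma::sum(gout, 0);
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// Fused instance normalization + LeakyReLU (the block's activation stage):
// one pass per direction instead of two.  LeakyReLU is sign-preserving, so
// the pre-activation sign needed by the backward pass is recovered from y.
// [[Rcpp::export]]
List cpp_inlrelu_fwd(const arma::mat& x, NumericVector gamma,
                     NumericVector beta, double eps, double slope) {
  const int N = x.n_rows, C = x.n_cols;
  Mat y(N, C);
  NumericVector mu(C), istd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double s = 0;
    for (int i = 0; i < N; ++i) s += xc[i];
    const double m = s / N;
    double v = 0;
    for (int i = 0; i < N; ++i) { const double d = xc[i] - m; v += d * d; }
    const double is = 1.0 / std::sqrt(v / N + eps);
    mu[c] = m; istd[c] = is;
    const double a = gamma[c] * is, b0 = beta[c] - a * m;
    double* yc = y.colptr(c);
    for (int i = 0; i < N; ++i) {
      const double z = a * xc[i] + b0;
      yc[i] = z >= 0 ? z : slope * z;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_inlrelu_bwd(const arma::mat& x, const arma::mat& y,
                     const arma::mat& g, NumericVector gamma,
                     NumericVector mu, NumericVector istd, double slope) {
  const int N = x.n_rows, C = x.n_cols;
  Mat gx(N, C);
  NumericVector gg(C), gb(C);
  std::vector<double> gz(N);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    const double* yc = y.colptr(c);
    const double* gc = g.colptr(c);
    const double m = mu[c], is = istd[c];
    double sg = 0, sgx = 0;
    for (int i = 0; i < N; ++i) {
      const double gi = yc[i] >= 0 ? gc[i] : slope * gc[i];
      gz[i] = gi;
      sg += gi;
      sgx += gi * (xc[i] - m) * is;
    }
    gg[c] = sgx; gb[c] = sg;
    const double a = gamma[c] * is;
    const double mg = sg / N, mgx = sgx / N;
    double* gxc = gx.colptr(c);
    for (int i = 0; i < N; ++i)
      gxc[i] = a * (gz[i] - mg - (xc[i] - m) * is * mgx);
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::mat& x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int Nout = mx * my * mz, C = x.n_cols;
  Mat out(Nout, C);
  arma::umat am(Nout, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* oc = out.colptr(c);
    arma::uword* ac = am.colptr(c);
    for (int iz = 0; iz < mz; ++iz)
      for (int iy = 0; iy < my; ++iy)
        for (int ixo = 0; ixo < mx; ++ixo) {
          double best = -1e300; int bidx = 0;
          for (int d = 0; d < 8; ++d) {
            const int jx = 2 * ixo + d % 2, jy = 2 * iy + (d / 2) % 2,
                      jz = 2 * iz + d / 4;
            const int j = jx + nx * (jy + ny * jz);
            if (xc[j] > best) { best = xc[j]; bidx = j; }
          }
          const int o = ixo + mx * (iy + my * iz);
          oc[o] = best; ac[o] = bidx;
        }
  }
  return List::create(_["out"] = out, _["argmax"] = am);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool2_bwd(const arma::umat& argmax, const arma::mat& gout,
                           int Nin) {
  const int C = gout.n_cols;
  Mat gx(Nin, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gc = gout.colptr(c);
    const arma::uword* ac = argmax.colptr(c);
    double* xc = gx.colptr(c);
    for (arma::uword i = 0; i < gout.n_rows; ++i) xc[ac[i]] += gc[i];
  }
  return gx;
}

// Naive double-precision reference convolution (used by tests as an
// independent oracle for the fast float32 path): direct triple-loop
// cross-correlation with zero padding.
// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd_ref(const arma::mat& x, IntegerVector dims,
                             NumericVector w, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int Cin = x.n_cols, Cout = b.size();
  Mat out(x.n_rows, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* oc = out.colptr(co);
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          double s = b[co];
          for (int d = 0; d < 27; ++d) {
            const int jx = ix + d % 3 - 1, jy = iy + (d / 3) % 3 - 1,
                      jz = iz + d / 9 - 1;
            if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny ||
                jz >= nz)
              continue;
            const R_xlen_t j = jx + nx * (jy + (R_xlen_t)ny * jz);
            for (int ci = 0; ci < Cin; ++ci)
              s += x(j, ci) * w[d + 27 * ci + 27 * Cin * co];
          }
          oc[ix + nx * (iy + (R_xlen_t)ny * iz)] = s;
        }
  }
  return out;
}

// Grid resampling with pixel-centre alignment: output voxel centre i maps to
// input continuous index (i + 0.5) * (n_in / n_out_eff) - 0.5 where the ratio
// is given per axis as `scale` = target_spacing / input_spacing.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector x, IntegerVector in_dims,
                           IntegerVector out_dims, NumericVector scale,
                           bool nearest) {
  const int nx = in_dims[0], ny = in_dims[1], nz = in_dims[2];
  const int ox = out_dims[0], oy = out_dims[1], oz = out_dims[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double* xs = x.begin();
  double* os = out.begin();
  for (int kz = 0; kz < oz; ++kz) {
    double cz = (kz + 0.5) * scale[2] - 0.5;
    cz = std::min(std::max(cz, 0.0), nz - 1.0);
    for (int ky = 0; ky < oy; ++ky) {
      double cy = (ky + 0.5) * scale[1] - 0.5;
      cy = std::min(std::max(cy, 0.0), ny - 1.0);
      for (int kx = 0; kx < ox; ++kx) {
        double cx = (kx + 0.5) * scale[0] - 0.5;
        cx = std::min(std::max(cx, 0.0), nx - 1.0);
        double v;
        if (nearest) {
          const int ix = (int)std::lround(cx), iy = (int)std::lround(cy),
                    iz = (int)std::lround(cz);
          v = xs[ix + nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy),
                    z0 = (int)std::floor(cz);
          const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
                    z1 = std::min(z0 + 1, nz - 1);
          const double fx = cx - x0, fy = cy - y0, fz = cz - z0;
          auto at = [&](int a, int b, int cI) {
            return xs[a + nx * (b + (R_xlen_t)ny * cI)];
          };
          const double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
          const double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
          const double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
          const double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          v = c0 * (1 - fz) + c1 * fz;
        }
        os[kx + ox * (ky + (R_xlen_t)oy * kz)] = v;
      }
    }
  }
  return out;
}

// Largest 26-connected component of a binary volume (iterative flood fill).
// [[Rcpp::export]]
IntegerVector cpp_largest_component(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(N, 0);
  IntegerVector out(N);
  int cur = 0, best_label = 0;
  R_xlen_t best_size = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (mask[s] == 0 || label[s] != 0) continue;
    ++cur;
    R_xlen_t size = 0;
    stack.push_back(s);
    label[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      ++size;
      const int ix = v % nx, iy = (v / nx) % ny, iz = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
              continue;
            const R_xlen_t j = jx + nx * (jy + (R_xlen_t)ny * jz);
            if (mask[j] != 0 && label[j] == 0) {
              label[j] = cur;
              stack.push_back(j);
            }
          }
    }
    if (size > best_size) { best_size = size; best_label = cur; }
  }
  for (R_xlen_t s = 0; s < N; ++s) out[s] = (label[s] == best_label && best_label) ? 1 : 0;
  return out;
}

// ---------------------------------------------------------------------------
// Thorax phantom renderer.
//
// Materials: 0 air, 1 soft tissue, 2 lung, 3 epicardial fat, 4 pericardial
// line, 5 heart core (blood/myocardium), 6 calcium, 7 paracardial fat,
// 8 subcutaneous chest fat.  A voxel is rendered as the mean HU of its
// supersampled sub-voxel centres (partial-volume mixing); occupancy fractions
// of the pericardial sac and of epicardial fat are returned alongside.
//
// Geometry parameters are passed in a flat named-order vector, see
// phantom_render() on the R side.
struct PhantomGeom {
  double bx, by, bz, bax, bay, baz;        // body ellipsoid
  double cx, cy, cz, a, b, c;              // pericardial sac
  double rho, delta;                        // core scale, line thickness frac
  double f_eq, f_apex, cap_frac;           // fat wedge fractions, apex cap
  double u0;                                // wedge centre angle
  double para;                              // 1 = render paracardial fat
  double para_frac;                         // paracardial shell relative width
  double lungdx, lax, lay, laz;            // lung offset/semi-axes
  double calr;                              // calcium radius (0 = none)
  double chest_frac;                       // subcutaneous fat layer frac
  double hu_air, hu_soft, hu_lung, hu_fat, hu_line, hu_core, hu_cal;
  double line_fade;                        // apex line HU blend toward soft
};

static int material_at(const PhantomGeom& g, double x, double y, double z,
                       bool* in_sac) {
  *in_sac = false;
  const double qb2 = std::pow((x - g.bx) / g.bax, 2) +
                     std::pow((y - g.by) / g.bay, 2) +
                     std::pow((z - g.bz) / g.baz, 2);
  if (qb2 > 1.0) return 0;  // outside body: air
  // pericardial sac, normalized radius
  const double ex = (x - g.cx) / g.a, ey = (y - g.cy) / g.b,
               ez = (z - g.cz) / g.c;
  const double q = std::sqrt(ex * ex + ey * ey + ez * ez);
  if (q <= 1.0) {
    *in_sac = true;
    if (g.calr > 0) {
      const double dc = std::sqrt(std::pow(x - g.cx, 2) + std::pow(y - g.cy, 2) +
                                  std::pow(z - (g.cz + 0.3 * g.c), 2));
      if (dc <= g.calr) return 6;
    }
    if (q > 1.0 - g.delta) return 4;       // pericardial line
    if (q <= g.rho) return 5;              // heart core
    // fat zone: angular wedge with axial (apex-cap) weighting
    const double zn = (z - (g.cz - g.c)) / (2.0 * g.c);  // 0 at apex
    const double f = (zn < g.cap_frac) ? g.f_apex : g.f_eq;
    double u = std::atan2(ey, ex) - g.u0;
    while (u > M_PI) u -= 2 * M_PI;
    while (u < -M_PI) u += 2 * M_PI;
    return (std::fabs(u) <= M_PI * f) ? 3 : 1;
  }
  // paracardial fat: thin shell hugging the sac, anterior wedge, plus
  // subcutaneous chest layer
  if (g.para > 0.5) {
    if (q <= 1.0 + g.para_frac) {
      double u = std::atan2(ey, ex);
      const double zn = (z - (g.cz - g.c)) / (2.0 * g.c);
      if (zn > 0.15 && std::fabs(u) <= 0.45 * M_PI) return 7;
    }
    if (qb2 > std::pow(1.0 - g.chest_frac, 2)) return 8;
  }
  // lungs: two ellipsoids flanking the heart
  for (int s = -1; s <= 1; s += 2) {
    const double lx = g.cx + s * g.lungdx;
    const double ql = std::pow((x - lx) / g.lax, 2) +
                      std::pow((y - g.cy) / g.lay, 2) +
                      std::pow((z - g.cz) / g.laz, 2);
    if (ql <= 1.0) return 2;
  }
  return 1;
}

static double material_hu(const PhantomGeom& g, int m, double z) {
  switch (m) {
    case 0: return g.hu_air;
    case 1: return g.hu_soft;
    case 2: return g.hu_lung;
    case 3: case 7: case 8: return g.hu_fat;
    case 4: {
      const double zn = (z - (g.cz - g.c)) / (2.0 * g.c);
      if (zn < g.cap_frac)  // faint apical boundary
        return g.hu_line + g.line_fade * (g.hu_soft - g.hu_line);
      return g.hu_line;
    }
    case 5: return g.hu_core;
    default: return g.hu_cal;
  }
}

// [[Rcpp::export]]
List cpp_phantom_render(IntegerVector dims, NumericVector spacing,
                        NumericVector p, int supersample) {
  static_assert(sizeof(PhantomGeom) == 34 * sizeof(double),
                "geometry parameter layout");
  PhantomGeom g;
  double* gp = reinterpret_cast<double*>(&g);
  for (int i = 0; i < (int)(sizeof(PhantomGeom) / sizeof(double)); ++i)
    gp[i] = p[i];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  NumericVector hu(N), sac_occ(N), fat_occ(N);
  IntegerVector mat(N);
  const int k = std::max(1, supersample);
  const double inv = 1.0 / (k * k * k);
  std::vector<int> counts(9);
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        double hsum = 0, sac = 0, fat = 0;
        std::fill(counts.begin(), counts.end(), 0);
        for (int az = 0; az < k; ++az) {
          const double z = (iz + (az + 0.5) / k) * spacing[2];
          for (int ay = 0; ay < k; ++ay) {
            const double y = (iy + (ay + 0.5) / k) * spacing[1];
            for (int ax = 0; ax < k; ++ax) {
              const double x = (ix + (ax + 0.5) / k) * spacing[0];
              bool in_sac = false;
              const int m = material_at(g, x, y, z, &in_sac);
              ++counts[m];
              hsum += material_hu(g, m, z);
              if (in_sac) sac += 1;
              if (m == 3) fat += 1;
            }
          }
        }
        const R_xlen_t o = ix + nx * (iy + (R_xlen_t)ny * iz);
        hu[o] = hsum * inv;
        sac_occ[o] = sac * inv;
        fat_occ[o] = fat * inv;
        int bm = 0, bc = -1;
        for (int m = 0; m < 9; ++m)
          if (counts[m] > bc) { bc = counts[m]; bm = m; }
        mat[o] = bm;
      }
  return List::create(_["hu"] = hu, _["sac_occ"] = sac_occ,
                      _["fat_occ"] = fat_occ, _["material"] = mat);
}
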