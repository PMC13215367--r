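#include <Rcpp.h>
#include <vector>
#ifdef __GNUC__
#pragma GCC optimize("O3", "unroll-loops")
#endif
using namespace Rcpp;

// 3D convolution kernels for volumes stored as R arrays in column-major
// order with dimensions (nx, ny, nz, channels).  Weights are
// (k, k, k, c_in, c_out).  Scalar stride and zero padding on all axes.
// Inputs are copied once into zero-padded buffers so the hot loops are
// branch-free, and loops are row-centric so each output row is written
// once while the kernel taps read from cache.  Correctness is pinned by
// finite-difference tests on the R side.

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// copy all channels into a zero-padded buffer (px, py, pz, ci)
static void pad_all(const double *X, int nx, int ny, int nz, int ci, int p,
                    std::vector<double> &buf) {
  const size_t px = nx + 2 * p, py = ny + 2 * p, pz = nz + 2 * p;
  buf.assign(px * py * pz * ci, 0.0);
  for (int a = 0; a < ci; ++a)
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const double *src = X + static_cast<size_t>(nx) * (y + static_cast<size_t>(ny) * z)
                              + static_cast<size_t>(nx) * ny * nz * a;
        double *dst = &buf[p + px * ((y + p) + py * (z + p)) + px * py * pz * a];
        for (int x = 0; x < nx; ++x) dst[x] = src[x];
      }
}

// [[Rcpp::export(name = ".conv3_fwd")]]
NumericVector conv3_fwd(NumericVector x, IntegerVector xdim,
                        NumericVector w, IntegerVector wdim,
                        NumericVector bias, int stride, int pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int k = wdim[0], co = wdim[4];
  const int ox = out_size(nx, k, stride, pad);
  const int oy = out_size(ny, k, stride, pad);
  const int oz = out_size(nz, k, stride, pad);
  const size_t px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  NumericVector y(static_cast<R_xlen_t>(ox) * oy * oz * co);
  const double *W = w.begin(), *B = bias.begin();
  double *Y = y.begin();
  const size_t yc = static_cast<size_t>(ox) * oy * oz;
  const size_t pc = px * py * pz;
  const int kk = k * k * k;
  std::vector<double> xp;
  pad_all(x.begin(), nx, ny, nz, ci, pad, xp);
  for (int c = 0; c < co; ++c) {
    double *Yc = Y + c * yc;
    for (int jz = 0; jz < oz; ++jz) {
      for (int jy = 0; jy < oy; ++jy) {
        double *__restrict yrow = Yc + static_cast<size_t>(ox) * (jy + static_cast<size_t>(oy) * jz);
        for (int jx = 0; jx < ox; ++jx) yrow[jx] = B[c];
        for (int a = 0; a < ci; ++a) {
          const double *Wa = W + (static_cast<size_t>(c) * ci + a) * kk;
          const double *xpa = &xp[pc * a];
          for (int kz = 0; kz < k; ++kz) {
            const size_t iz = static_cast<size_t>(jz) * stride + kz;
            for (int ky = 0; ky < k; ++ky) {
              const size_t iy = static_cast<size_t>(jy) * stride + ky;
              const double *row = xpa + px * (iy + py * iz);
              const double *wrow = Wa + k * (ky + k * kz);
              if (stride == 1 && k == 3) {
                // vectorizable shifted AXPY triple on the L1-resident row
                const double w0 = wrow[0], w1 = wrow[1], w2 = wrow[2];
                for (int jx = 0; jx < ox; ++jx)
                  yrow[jx] += w0 * row[jx] + w1 * row[jx + 1] + w2 * row[jx + 2];
              } else {
                for (int jx = 0; jx < ox; ++jx) {
                  const double *src = row + static_cast<size_t>(jx) * stride;
                  double acc = 0.0;
                  for (int kx = 0; kx < k; ++kx) acc += wrow[kx] * src[kx];
                  yrow[jx] += acc;
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, co);
  return y;
}

// Gradient w.r.t. the input: scatter output-gradient rows through the
// kernel taps into a padded buffer, then crop.  Also the forward pass
// of the transposed convolution.
// [[Rcpp::export(name = ".conv3_bwd_input")]]
NumericVector conv3_bwd_input(NumericVector gy, IntegerVector ydim,
                              NumericVector w, IntegerVector wdim,
                              IntegerVector xdim, int stride, int pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int k = wdim[0], co = wdim[4];
  const int ox = ydim[0], oy = ydim[1], oz = ydim[2];
  const size_t px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  NumericVector gx(static_cast<R_xlen_t>(nx) * ny * nz * ci);
  const double *GY = gy.begin(), *W = w.begin();
  double *GX = gx.begin();
  const size_t xc = static_cast<size_t>(nx) * ny * nz;
  const size_t yc = static_cast<size_t>(ox) * oy * oz;
  const int kk = k * k * k;
  std::vector<double> gp;
  for (int a = 0; a < ci; ++a) {
    gp.assign(px * py * pz, 0.0);
    for (int jz = 0; jz < oz; ++jz) {
      for (int jy = 0; jy < oy; ++jy) {
        for (int c = 0; c < co; ++c) {
          const double *grow = GY + c * yc +
            static_cast<size_t>(ox) * (jy + static_cast<size_t>(oy) * jz);
          const double *Wa = W + (static_cast<size_t>(c) * ci + a) * kk;
          for (int kz = 0; kz < k; ++kz) {
            const size_t iz = static_cast<size_t>(jz) * stride + kz;
            for (int ky = 0; ky < k; ++ky) {
              const size_t iy = static_cast<size_t>(jy) * stride + ky;
              double *row = &gp[px * (iy + py * iz)];
              const double *wrow = Wa + k * (ky + k * kz);
              if (stride == 1 && k == 3) {
                const double w0 = wrow[0], w1 = wrow[1], w2 = wrow[2];
                double *__restrict d0 = row;
                for (int jx = 0; jx < ox; ++jx) d0[jx] += w0 * grow[jx];
                double *__restrict d1 = row + 1;
                for (int jx = 0; jx < ox; ++jx) d1[jx] += w1 * grow[jx];
                double *__restrict d2 = row + 2;
                for (int jx = 0; jx < ox; ++jx) d2[jx] += w2 * grow[jx];
              } else {
                for (int jx = 0; jx < ox; ++jx) {
                  double *dst = row + static_cast<size_t>(jx) * stride;
                  const double g = grow[jx];
                  for (int kx = 0; kx < k; ++kx) dst[kx] += wrow[kx] * g;
                }
              }
            }
          }
        }
      }
    }
    double *Ga = GX + a * xc;
    for (int z = 0; z < nz; ++z)
      for (int y2 = 0; y2 < ny; ++y2) {
        const double *src = &gp[pad + px * ((y2 + pad) + py * (z + pad))];
        double *dst = Ga + static_cast<size_t>(nx) * (y2 + static_cast<size_t>(ny) * z);
        for (int x2 = 0; x2 < nx; ++x2) dst[x2] += src[x2];
      }
  }
  gx.attr("dim") = xdim;
  return gx;
}

// Gradient w.r.t. the weights: per (input-channel, output-channel) pair
// the output gradient is streamed once, accumulating all k^3 taps in
// local registers.
// [[Rcpp::export(name = ".conv3_bwd_weight")]]
NumericVector conv3_bwd_weight(NumericVector x, IntegerVector xdim,
                               NumericVector gy, IntegerVector ydim,
                               IntegerVector wdim, int stride, int pad) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], ci = xdim[3];
  const int k = wdim[0], co = wdim[4];
  const int ox = ydim[0], oy = ydim[1], oz = ydim[2];
  const size_t px = nx + 2 * pad, py = ny + 2 * pad, pz = nz + 2 * pad;
  NumericVector gw(static_cast<R_xlen_t>(k) * k * k * ci * co);
  const double *X = x.begin(), *GY = gy.begin();
  double *GW = gw.begin();
  const size_t yc = static_cast<size_t>(ox) * oy * oz;
  const size_t pc = px * py * pz;
  const int kk = k * k * k;
  std::vector<double> xp;
  pad_all(X, nx, ny, nz, ci, pad, xp);
  std::vector<double> acc(kk);
  for (int c = 0; c < co; ++c) {
    const double *Gc = GY + c * yc;
    for (int a = 0; a < ci; ++a) {
      const double *xpa = &xp[pc * a];
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int jz = 0; jz < oz; ++jz) {
        for (int jy = 0; jy < oy; ++jy) {
          const double *grow = Gc + static_cast<size_t>(ox) * (jy + static_cast<size_t>(oy) * jz);
          for (int kz = 0; kz < k; ++kz) {
            const size_t iz = static_cast<size_t>(jz) * stride + kz;
            for (int ky = 0; ky < k; ++ky) {
              const size_t iy = static_cast<size_t>(jy) * stride + ky;
              const double *row = xpa + px * (iy + py * iz);
              double *arow = &acc[k * (ky + k * kz)];
              if (stride == 1 && k == 3) {
                double a0 = 0.0, a1 = 0.0, a2 = 0.0;
                for (int jx = 0; jx < ox; ++jx) {
                  const double g = grow[jx];
                  a0 += g * row[jx]; a1 += g * row[jx + 1]; a2 += g * row[jx + 2];
                }
                arow[0] += a0; arow[1] += a1; arow[2] += a2;
              } else {
                for (int jx = 0; jx < ox; ++jx) {
                  const double *src = row + static_cast<size_t>(jx) * stride;
                  const double g = grow[jx];
                  for (int kx = 0; kx < k; ++kx) arow[kx] += g * src[kx];
                }
              }
            }
          }
        }
      }
      double *Wa = GW + (static_cast<size_t>(c) * ci + a) * kk;
      for (int t = 0; t < kk; ++t) Wa[t] += acc[t];
    }
  }
  gw.attr("dim") = wdim;
  return gw;
}

// Instance normalization over the spatial dims of an (nx,ny,nz,C)
// array: per channel, y = gamma * (x - mean) / sqrt(var + eps) + beta.
// Returns the output plus the normalized values and inverse SDs needed
// by the backward pass.
// [[Rcpp::export(name = ".inorm_fwd")]]
List inorm_fwd(NumericVector x, IntegerVector xdim,
               NumericVector gamma, NumericVector beta, double eps) {
  const R_xlen_t nvox = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector y(x.size()), xh(x.size()), isd(C);
  const double *X = x.begin();
  double *Y = y.begin(), *XH = xh.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = X + c * nvox;
    double mu = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) mu += xc[i];
    mu /= nvox;
    double va = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) { const double d = xc[i] - mu; va += d * d; }
    va /= nvox;
    const double is = 1.0 / std::sqrt(va + eps);
    isd[c] = is;
    const double g = gamma[c], b = beta[c];
    double *yc = Y + c * nvox, *hc = XH + c * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i) {
      const double h = (xc[i] - mu) * is;
      hc[i] = h;
      yc[i] = g * h + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(_["y"] = y, _["xh"] = xh, _["isd"] = isd);
}

// [[Rcpp::export(name = ".inorm_bwd")]]
List inorm_bwd(NumericVector g, NumericVector xh, NumericVector isd,
               NumericVector gamma, IntegerVector xdim) {
  const R_xlen_t nvox = static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2];
  const int C = xdim[3];
  NumericVector gx(g.size()), ggam(C), gbet(C);
  const double *G = g.begin(), *XH = xh.begin();
  double *GX = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = G + c * nvox, *hc = XH + c * nvox;
    double sg = 0.0, sgh = 0.0;
    for (R_xlen_t i = 0; i < nvox; ++i) { sg += gc[i]; sgh += gc[i] * hc[i]; }
    ggam[c] = sgh;
    gbet[c] = sg;
    const double gamc = gamma[c], is = isd[c];
    const double mg = sg / nvox, mgh = sgh / nvox;
    double *gxc = GX + c * nvox;
    for (R_xlen_t i = 0; i < nvox; ++i)
      gxc[i] = gamc * is * (gc[i] - mg - hc[i] * mgh);
  }
  gx.attr("dim") = xdim;
  return List::create(_["gx"] = gx, _["ggamma"] = ggam, _["gbeta"] = gbet);
}

// leaky ReLU forward/backward, single pass, no temporaries
// [[Rcpp::export(name = ".lrelu_fwd")]]
NumericVector lrelu_fwd(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double *X = x.begin();
  double *Y = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    Y[i] = X[i] > 0 ? X[i] : slope * X[i];
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".lrelu_bwd")]]
NumericVector lrelu_bwd(NumericVector g, NumericVector x, double slope) {
  NumericVector gx(g.size());
  const double *G = g.begin(), *X = x.begin();
  double *GX = gx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i)
    GX[i] = X[i] > 0 ? G[i] : slope * G[i];
  gx.attr("dim") = x.attr("dim");
  return gx;
}

// Max over non-overlapping p^3 patches of a single-channel volume.
// Returns the patch maxima and the 1-based linear argmax indices so the
// backward pass can route gradients; ties resolved to the first voxel
// in raster order (deterministic).
// [[Rcpp::export(name = ".patchmax_fwd")]]
List patchmax_fwd(NumericVector x, IntegerVector xdim, int p) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  const int gx = nx / p, gy = ny / p, gz = nz / p;
  NumericVector q(static_cast<R_xlen_t>(gx) * gy * gz);
  IntegerVector idx(q.size());
  const double *X = x.begin();
  R_xlen_t out = 0;
  for (int cz = 0; cz < gz; ++cz) {
    for (int cy = 0; cy < gy; ++cy) {
      for (int cx = 0; cx < gx; ++cx) {
        double best = R_NegInf;
        R_xlen_t bi = -1;
        for (int iz = cz * p; iz < (cz + 1) * p; ++iz) {
          for (int iy = cy * p; iy < (cy + 1) * p; ++iy) {
            for (int ix = cx * p; ix < (cx + 1) * p; ++ix) {
              const R_xlen_t li = ix + static_cast<R_xlen_t>(nx) * (iy + static_cast<R_xlen_t>(ny) * iz);
              if (X[li] > best) { best = X[li]; bi = li; }
            }
          }
        }
        q[out] = best;
        idx[out] = static_cast<int>(bi) + 1;
        ++out;
      }
    }
  }
  q.attr("dim") = IntegerVector::create(gx, gy, gz);
  return List::create(_["q"] = q, _["idx"] = idx);
}

// [[Rcpp::export(name = ".patchmax_bwd")]]
NumericVector patchmax_bwd(NumericVector gq, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2]);
  for (R_xlen_t i = 0; i < gq.size(); ++i) gx[idx[i] - 1] += gq[i];
  gx.attr("dim") = IntegerVector::create(xdim[0], xdim[1], xdim[2]);
  return gx;
}
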