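// Z-preserving encoder-decoder ("U-Net") engine for paired DWI/ADC volumes.
//
// Activations are stored as arma::fmat with one row per voxel
// (x fastest, then y, then z) and one column per channel. Convolutions are
// cross-correlations with 3x3 in-plane extent and z extent kz (1 for the 2D
// variant, 3 for the 3D variant), zero padded so the output grid equals the
// input grid. Pooling and upsampling act only in x and y; z is never mixed
// except by the kz=3 kernels, which is what makes the network applicable to
// an arbitrary number of axial slices.
//
// Single precision throughout: the training loop is GEMM-bound and sgemm is
// twice dgemm throughput; parameters cross the R boundary as doubles.

#include <RcppArmadillo.h>
#include <cstring>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// ---------------------------------------------------------------------------
// im2col / col2im for one axial output slice.
// col has one row per in-plane voxel (x fastest) and one column per kernel
// tap k = dx + 3*(dy + 3*(dz + kz*cin)), matching the flattening of an R
// weight array of dim (3, 3, kz, Cin, Cout).

static void im2col_slice(const fmat& A, int nx, int ny, int nz, int Cin,
                         int kz, int z, fmat& col) {
  const int nxy = nx * ny, cz = kz / 2;
  col.zeros();
  for (int cin = 0; cin < Cin; ++cin) {
    const float* Ac = A.colptr(cin);
    for (int dz = 0; dz < kz; ++dz) {
      const int zz = z + dz - cz;
      if (zz < 0 || zz >= nz) continue;
      const float* As = Ac + (size_t)zz * nxy;
      for (int dy = 0; dy < 3; ++dy) {
        const int sy = dy - 1;
        const int y0 = std::max(0, -sy), y1 = std::min(ny, ny - sy);
        for (int dx = 0; dx < 3; ++dx) {
          const int sx = dx - 1;
          const int x0 = std::max(0, -sx), x1 = std::min(nx, nx - sx);
          const int len = x1 - x0;
          if (len <= 0) continue;
          const int k = dx + 3 * (dy + 3 * (dz + kz * cin));
          float* ck = col.colptr(k);
          for (int y = y0; y < y1; ++y) {
            std::memcpy(ck + (size_t)y * nx + x0,
                        As + (size_t)(y + sy) * nx + (x0 + sx),
                        len * sizeof(float));
          }
        }
      }
    }
  }
}

static void col2im_add_slice(fmat& dA, int nx, int ny, int nz, int Cin,
                             int kz, int z, const fmat& dcol) {
  const int nxy = nx * ny, cz = kz / 2;
  for (int cin = 0; cin < Cin; ++cin) {
    float* Ac = dA.colptr(cin);
    for (int dz = 0; dz < kz; ++dz) {
      const int zz = z + dz - cz;
      if (zz < 0 || zz >= nz) continue;
      float* As = Ac + (size_t)zz * nxy;
      for (int dy = 0; dy < 3; ++dy) {
        const int sy = dy - 1;
        const int y0 = std::max(0, -sy), y1 = std::min(ny, ny - sy);
        for (int dx = 0; dx < 3; ++dx) {
          const int sx = dx - 1;
          const int x0 = std::max(0, -sx), x1 = std::min(nx, nx - sx);
          const int len = x1 - x0;
          if (len <= 0) continue;
          const int k = dx + 3 * (dy + 3 * (dz + kz * cin));
          const float* ck = dcol.colptr(k);
          for (int y = y0; y < y1; ++y) {
            float* dst = As + (size_t)(y + sy) * nx + (x0 + sx);
            const float* src = ck + (size_t)y * nx + x0;
            for (int i = 0; i < len; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
}

static fmat conv_forward(const fmat& A, const fmat& W, const fvec& b,
                         int nx, int ny, int nz, int kz) {
  const int nxy = nx * ny, Cout = W.n_cols;
  const int Cin = A.n_cols;
  fmat out(A.n_rows, Cout);
  fmat col(nxy, W.n_rows);
  for (int z = 0; z < nz; ++z) {
    im2col_slice(A, nx, ny, nz, Cin, kz, z, col);
    out.rows((size_t)z * nxy, (size_t)z * nxy + nxy - 1) = col * W;
  }
  out.each_row() += b.t();
  return out;
}

static void conv_backward(const fmat& A, const fmat& W, const fmat& dOut,
                          int nx, int ny, int nz, int kz,
                          fmat& dW, fvec& db, fmat& dA) {
  const int nxy = nx * ny;
  const int Cin = A.n_cols;
  dW.zeros(W.n_rows, W.n_cols);
  dA.zeros(A.n_rows, A.n_cols);
  fmat col(nxy, W.n_rows);
  for (int z = 0; z < nz; ++z) {
    const fmat dY = dOut.rows((size_t)z * nxy, (size_t)z * nxy + nxy - 1);
    im2col_slice(A, nx, ny, nz, Cin, kz, z, col);
    dW += col.t() * dY;
    const fmat dcol = dY * W.t();
    col2im_add_slice(dA, nx, ny, nz, Cin, kz, z, dcol);
  }
  db = arma::sum(dOut, 0).t();
}

// ---------------------------------------------------------------------------
// xy max-pooling (factor 2) with argmax bookkeeping; z untouched.

static fmat maxpool_forward(const fmat& A, int nx, int ny, int nz,
                            arma::umat& argmax) {
  const int hx = nx / 2, hy = ny / 2;
  const int nxy = nx * ny, hxy = hx * hy;
  const int C = A.n_cols;
  fmat out((size_t)hxy * nz, C);
  argmax.set_size((size_t)hxy * nz, C);
  for (int c = 0; c < C; ++c) {
    const float* Ac = A.colptr(c);
    float* Oc = out.colptr(c);
    uword* Mc = argmax.colptr(c);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < hy; ++y) {
        for (int x = 0; x < hx; ++x) {
          const size_t base = (size_t)z * nxy + (size_t)(2 * y) * nx + 2 * x;
          size_t best = base;
          float v = Ac[base];
          if (Ac[base + 1] > v) { v = Ac[base + 1]; best = base + 1; }
          if (Ac[base + nx] > v) { v = Ac[base + nx]; best = base + nx; }
          if (Ac[base + nx + 1] > v) { v = Ac[base + nx + 1]; best = base + nx + 1; }
          const size_t o = (size_t)z * hxy + (size_t)y * hx + x;
          Oc[o] = v;
          Mc[o] = best;
        }
      }
    }
  }
  return out;
}

static fmat maxpool_backward(const fmat& dOut, const arma::umat& argmax,
                             size_t in_rows) {
  fmat dA(in_rows, dOut.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dOut.n_cols; ++c) {
    const float* dOc = dOut.colptr(c);
    const uword* Mc = argmax.colptr(c);
    float* dAc = dA.colptr(c);
    for (uword o = 0; o < dOut.n_rows; ++o) dAc[Mc[o]] += dOc[o];
  }
  return dA;
}

// nearest-neighbour xy upsampling (factor 2)

static fmat upsample_forward(const fmat& A, int nx, int ny, int nz) {
  const int ux = 2 * nx, uy = 2 * ny;
  const int nxy = nx * ny, uxy = ux * uy;
  const int C = A.n_cols;
  fmat out((size_t)uxy * nz, C);
  for (int c = 0; c < C; ++c) {
    const float* Ac = A.colptr(c);
    float* Oc = out.colptr(c);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < uy; ++y) {
        const float* row = Ac + (size_t)z * nxy + (size_t)(y / 2) * nx;
        float* orow = Oc + (size_t)z * uxy + (size_t)y * ux;
        for (int x = 0; x < ux; ++x) orow[x] = row[x / 2];
      }
    }
  }
  return out;
}

static fmat upsample_backward(const fmat& dOut, int nx, int ny, int nz) {
  // nx, ny are the (smaller) input dims of the forward upsample
  const int ux = 2 * nx, uy = 2 * ny;
  const int nxy = nx * ny, uxy = ux * uy;
  const int C = dOut.n_cols;
  fmat dA((size_t)nxy * nz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dAc = dA.colptr(c);
    const float* dOc = dOut.colptr(c);
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < uy; ++y) {
        float* row = dAc + (size_t)z * nxy + (size_t)(y / 2) * nx;
        const float* orow = dOc + (size_t)z * uxy + (size_t)y * ux;
        for (int x = 0; x < ux; ++x) row[x / 2] += orow[x];
      }
    }
  }
  return dA;
}

// ---------------------------------------------------------------------------
// parameter bundle for one conv + batchnorm + leaky-ReLU block

struct BlkW {
  fmat W;
  fvec b, gamma, beta, rmean, rvar;
};

struct BlockCache {
  fmat in;      // block input (for conv backward)
  fmat xhat;    // normalized conv output (for BN backward)
  fvec invstd;  // per-channel 1/sqrt(var + eps) actually used
  fmat out;     // post-activation output
  int nx, ny;
};

struct NetCache {
  int nx, ny, nz, depth, kz, in_channels, base_channels;
  float slope;
  bool training;
  std::vector<std::string> names;
  std::vector<BlkW> par;
  fmat outW;
  float outb;
  std::vector<BlockCache> blocks;
  std::vector<arma::umat> pool_argmax;
  std::vector<size_t> pool_in_rows;
  fmat last_act;  // input of the 1x1x1 output conv
  fmat prob;      // sigmoid output (single column)
  std::vector<fvec> new_rmean, new_rvar;
};

static std::vector<std::string> block_names(int depth) {
  std::vector<std::string> nm;
  for (int l = 1; l <= depth; ++l) {
    nm.push_back("enc" + std::to_string(l) + "_c1");
    nm.push_back("enc" + std::to_string(l) + "_c2");
  }
  nm.push_back("bot_c1");
  nm.push_back("bot_c2");
  for (int l = depth; l >= 1; --l) {
    nm.push_back("dec" + std::to_string(l) + "_c1");
    nm.push_back("dec" + std::to_string(l) + "_c2");
  }
  return nm;
}

static fmat as_fmat(SEXP s, int nrow, int ncol) {
  NumericVector v(s);
  if ((int)v.size() != nrow * ncol)
    stop("weight tensor has unexpected size");
  fmat M(nrow, ncol);
  for (int i = 0; i < nrow * ncol; ++i) M[i] = (float)v[i];
  return M;
}

static fvec as_fvec(SEXP s) {
  NumericVector v(s);
  fvec x(v.size());
  for (int i = 0; i < (int)v.size(); ++i) x[i] = (float)v[i];
  return x;
}

// forward through one conv block; fills cache when keep is set.
// A is taken by value and moved into the cache so chained blocks avoid
// redundant copies of full-resolution activations.
static fmat block_forward(fmat A, const BlkW& P, int nx, int ny, int nz,
                          int kz, bool training, float slope, bool keep,
                          BlockCache& C, fvec& new_rm, fvec& new_rv) {
  fmat y = conv_forward(A, P.W, P.b, nx, ny, nz, kz);
  if (keep) {
    C.in = std::move(A);
    C.nx = nx;
    C.ny = ny;
  }
  const int Cc = y.n_cols;
  const float N = (float)y.n_rows;
  C.invstd.set_size(Cc);
  if (training) {
    new_rm.set_size(Cc);
    new_rv.set_size(Cc);
    for (int c = 0; c < Cc; ++c) {
      auto col = y.col(c);
      const float mu = arma::mean(col);
      col -= mu;
      const float var = arma::dot(col, col) / N;
      const float inv = 1.0f / std::sqrt(var + BN_EPS);
      C.invstd[c] = inv;
      new_rm[c] = (1.0f - BN_MOMENTUM) * P.rmean[c] + BN_MOMENTUM * mu;
      new_rv[c] = (1.0f - BN_MOMENTUM) * P.rvar[c] + BN_MOMENTUM * var;
      col *= inv;
    }
  } else {
    for (int c = 0; c < Cc; ++c) {
      const float inv = 1.0f / std::sqrt(P.rvar[c] + BN_EPS);
      C.invstd[c] = inv;
      auto col = y.col(c);
      col -= P.rmean[c];
      col *= inv;
    }
  }
  if (keep) C.xhat = y;
  for (int c = 0; c < Cc; ++c) {
    float* yc = y.colptr(c);
    const float g = P.gamma[c], be = P.beta[c];
    for (uword i = 0; i < y.n_rows; ++i) {
      float v = g * yc[i] + be;
      yc[i] = v > 0.0f ? v : slope * v;
    }
  }
  if (keep) C.out = y;
  return y;
}

// backward through one conv block; returns gradient w.r.t. the block input
static fmat block_backward(const BlkW& P, const BlockCache& C, const fmat& dOut,
                           int nz, int kz, bool training, float slope,
                           fmat& dW, fvec& db, fvec& dgamma, fvec& dbeta) {
  const int Cc = dOut.n_cols;
  const float N = (float)dOut.n_rows;
  fmat dy = dOut;
  // leaky ReLU backward (post-activation sign equals pre-activation sign)
  for (int c = 0; c < Cc; ++c) {
    float* dc = dy.colptr(c);
    const float* oc = C.out.colptr(c);
    for (uword i = 0; i < dy.n_rows; ++i)
      if (oc[i] <= 0.0f) dc[i] *= slope;
  }
  // batchnorm backward
  dgamma.set_size(Cc);
  dbeta.set_size(Cc);
  fmat dconv(dy.n_rows, Cc);
  for (int c = 0; c < Cc; ++c) {
    auto dc = dy.col(c);
    auto xh = C.xhat.col(c);
    const float sg = arma::dot(dc, xh);
    const float sb = arma::accu(dc);
    dgamma[c] = sg;
    dbeta[c] = sb;
    const float g = P.gamma[c], inv = C.invstd[c];
    if (training) {
      dconv.col(c) = (g * inv) * (dc - (sb / N) - xh * (sg / N));
    } else {
      dconv.col(c) = (g * inv) * dc;
    }
  }
  fmat dA;
  conv_backward(C.in, P.W, dconv, C.nx, C.ny, nz, kz, dW, db, dA);
  return dA;
}

// ---------------------------------------------------------------------------

static List run_forward(NetCache& N, List weights, NumericVector x, int depth,
                        int kz, int in_channels, int base_channels,
                        double slope, bool training, bool keep_cache) {
  IntegerVector dm = x.attr("dim");
  const int nx = dm[0], ny = dm[1], nz = dm[2], Cin = dm[3];
  N.nx = nx; N.ny = ny; N.nz = nz; N.depth = depth; N.kz = kz;
  N.in_channels = in_channels; N.base_channels = base_channels;
  N.slope = (float)slope;
  N.training = training;
  N.names = block_names(depth);

  // parse weights in block order
  for (const std::string& nm : N.names) {
    NumericVector Wv = weights[nm + "_W"];
    IntegerVector wd = Wv.attr("dim");
    const int K = wd[0] * wd[1] * wd[2] * wd[3];
    const int Cout = wd[4];
    if (wd[2] != kz) stop("weight z extent does not match requested variant");
    BlkW P;
    P.W = as_fmat(Wv, K, Cout);
    P.b = as_fvec(weights[nm + "_b"]);
    P.gamma = as_fvec(weights[nm + "_gamma"]);
    P.beta = as_fvec(weights[nm + "_beta"]);
    P.rmean = as_fvec(weights[nm + "_rmean"]);
    P.rvar = as_fvec(weights[nm + "_rvar"]);
    N.par.push_back(P);
  }
  NumericVector outWv = weights["out_W"];
  IntegerVector od = outWv.attr("dim");
  N.outW = as_fmat(outWv, od[0], od[1]);
  N.outb = (float)NumericVector(weights["out_b"])[0];

  // input as fmat
  const size_t nvox = (size_t)nx * ny * nz;
  fmat A(nvox, Cin);
  for (size_t i = 0; i < nvox * Cin; ++i) A[i] = (float)x[i];

  N.blocks.resize(N.names.size());
  N.new_rmean.resize(N.names.size());
  N.new_rvar.resize(N.names.size());

  std::vector<fmat> skip(depth + 1);
  int cx = nx, cy = ny;
  int bi = 0;
  for (int l = 1; l <= depth; ++l) {
    A = block_forward(std::move(A), N.par[bi], cx, cy, nz, kz, training, N.slope,
                      keep_cache, N.blocks[bi], N.new_rmean[bi],
                      N.new_rvar[bi]);
    ++bi;
    A = block_forward(std::move(A), N.par[bi], cx, cy, nz, kz, training, N.slope,
                      keep_cache, N.blocks[bi], N.new_rmean[bi],
                      N.new_rvar[bi]);
    ++bi;
    skip[l] = A;
    arma::umat am;
    N.pool_in_rows.push_back(A.n_rows);
    A = maxpool_forward(A, cx, cy, nz, am);
    if (keep_cache) N.pool_argmax.push_back(am);
    cx /= 2; cy /= 2;
  }
  A = block_forward(std::move(A), N.par[bi], cx, cy, nz, kz, training, N.slope,
                    keep_cache, N.blocks[bi], N.new_rmean[bi],
                    N.new_rvar[bi]);
  ++bi;
  A = block_forward(std::move(A), N.par[bi], cx, cy, nz, kz, training, N.slope,
                    keep_cache, N.blocks[bi], N.new_rmean[bi],
                    N.new_rvar[bi]);
  ++bi;
  for (int l = depth; l >= 1; --l) {
    A = upsample_forward(A, cx, cy, nz);
    cx *= 2; cy *= 2;
    A = arma::join_rows(A, skip[l]);
    skip[l].reset();
    A = block_forward(std::move(A), N.par[bi], cx, cy, nz, kz, training, N.slope,
                      keep_cache, N.blocks[bi], N.new_rmean[bi],
                      N.new_rvar[bi]);
    ++bi;
    A = block_forward(std::move(A), N.par[bi], cx, cy, nz, kz, training, N.slope,
                      keep_cache, N.blocks[bi], N.new_rmean[bi],
                      N.new_rvar[bi]);
    ++bi;
  }
  fmat logits = A * N.outW;
  logits += N.outb;
  fmat prob = 1.0f / (1.0f + arma::exp(-logits));
  if (keep_cache) {
    N.last_act = A;
    N.prob = prob;
  }

  NumericVector out(nvox);
  for (size_t i = 0; i < nvox; ++i) out[i] = (double)prob[i];
  out.attr("dim") = IntegerVector::create(nx, ny, nz);

  List bn_updates = R_NilValue;
  if (training) {
    List upd;
    for (size_t i = 0; i < N.names.size(); ++i) {
      upd[N.names[i] + "_rmean"] = NumericVector(N.new_rmean[i].begin(),
                                                 N.new_rmean[i].end());
      upd[N.names[i] + "_rvar"] = NumericVector(N.new_rvar[i].begin(),
                                                N.new_rvar[i].end());
    }
    bn_updates = upd;
  }
  return List::create(_["prob"] = out, _["bn_updates"] = bn_updates);
}

// [[Rcpp::export]]
List unet_forward_cpp(List weights, NumericVector x, int depth, int kz,
                      int in_channels, int base_channels, double slope,
                      bool training, bool keep_cache) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("input must have dim (nx, ny, nz, channels)");
  const int nx = dm[0], ny = dm[1], nz = dm[2], Cin = dm[3];
  (void)nz;
  if (Cin != in_channels) stop("input channel count does not match spec");
  const int div = 1 << depth;
  if (nx % div != 0 || ny % div != 0)
    stop("x and y dimensions must be divisible by 2^depth");
  if (kz != 1 && kz != 3) stop("kernel z extent must be 1 or 3");

  if (keep_cache) {
    XPtr<NetCache> cache(new NetCache(), true);
    List res = run_forward(*cache, weights, x, depth, kz, in_channels,
                           base_channels, slope, training, true);
    return List::create(_["prob"] = res["prob"], _["cache"] = cache,
                        _["bn_updates"] = res["bn_updates"]);
  }
  NetCache local;
  return run_forward(local, weights, x, depth, kz, in_channels, base_channels,
                     slope, training, false);
}

// [[Rcpp::export]]
List unet_backward_cpp(SEXP cache_ptr, NumericVector dprob) {
  XPtr<NetCache> cache(cache_ptr);
  NetCache& N = *cache;
  if (N.blocks.empty()) stop("cache has already been consumed");
  const size_t nvox = (size_t)N.nx * N.ny * N.nz;
  if (dprob.size() != (R_xlen_t)nvox) stop("gradient has wrong size");

  fmat dlog(nvox, 1);
  for (size_t i = 0; i < nvox; ++i)
    dlog[i] = (float)dprob[i] * N.prob[i] * (1.0f - N.prob[i]);

  List grads;
  // output conv
  fmat dOutW = N.last_act.t() * dlog;
  double doutb = arma::accu(dlog);
  fmat dA = dlog * N.outW.t();

  const int depth = N.depth, nz = N.nz, kz = N.kz;
  int bi = (int)N.names.size() - 1;
  int cx = N.nx, cy = N.ny;
  std::vector<fmat> dskip(depth + 1);
  std::vector<fmat> gW(N.names.size());
  std::vector<fvec> gb(N.names.size()), gg(N.names.size()), gbe(N.names.size());

  for (int l = 1; l <= depth; ++l) {
    dA = block_backward(N.par[bi], N.blocks[bi], dA, nz, kz, N.training,
                        N.slope, gW[bi], gb[bi], gg[bi], gbe[bi]);
    --bi;
    dA = block_backward(N.par[bi], N.blocks[bi], dA, nz, kz, N.training,
                        N.slope, gW[bi], gb[bi], gg[bi], gbe[bi]);
    --bi;
    // dec{l}_c1 input was join_rows(up, skip[l]); split by known widths:
    // skip[l] is the enc{l}_c2 output, base_channels * 2^(l-1) channels.
    const int ch_skip_l = N.base_channels << (l - 1);
    fmat dUp = dA.cols(0, dA.n_cols - ch_skip_l - 1);
    dskip[l] = dA.cols(dA.n_cols - ch_skip_l, dA.n_cols - 1);
    dA = upsample_backward(dUp, cx / 2, cy / 2, nz);
    cx /= 2; cy /= 2;
  }
  // bottleneck
  dA = block_backward(N.par[bi], N.blocks[bi], dA, nz, kz, N.training, N.slope,
                      gW[bi], gb[bi], gg[bi], gbe[bi]);
  --bi;
  dA = block_backward(N.par[bi], N.blocks[bi], dA, nz, kz, N.training, N.slope,
                      gW[bi], gb[bi], gg[bi], gbe[bi]);
  --bi;
  // encoder, deepest level first
  for (int l = depth; l >= 1; --l) {
    dA = maxpool_backward(dA, N.pool_argmax[l - 1], N.pool_in_rows[l - 1]);
    dA += dskip[l];
    dskip[l].reset();
    dA = block_backward(N.par[bi], N.blocks[bi], dA, nz, kz, N.training,
                        N.slope, gW[bi], gb[bi], gg[bi], gbe[bi]);
    --bi;
    dA = block_backward(N.par[bi], N.blocks[bi], dA, nz, kz, N.training,
                        N.slope, gW[bi], gb[bi], gg[bi], gbe[bi]);
    --bi;
    cx *= 2; cy *= 2;
  }

  for (size_t i = 0; i < N.names.size(); ++i) {
    const std::string& nm = N.names[i];
    const int Cin_blk = (int)N.blocks[i].in.n_cols;
    NumericVector W(gW[i].begin(), gW[i].end());
    W.attr("dim") = IntegerVector::create(3, 3, kz, Cin_blk,
                                          (int)gW[i].n_cols);
    grads[nm + "_W"] = W;
    grads[nm + "_b"] = NumericVector(gb[i].begin(), gb[i].end());
    grads[nm + "_gamma"] = NumericVector(gg[i].begin(), gg[i].end());
    grads[nm + "_beta"] = NumericVector(gbe[i].begin(), gbe[i].end());
  }
  NumericVector oW(dOutW.begin(), dOutW.end());
  oW.attr("dim") = IntegerVector::create((int)dOutW.n_rows, 1);
  grads["out_W"] = oW;
  grads["out_b"] = NumericVector::create(doutb);

  // free the bulky caches now rather than at GC time
  N.blocks.clear();
  N.blocks.shrink_to_fit();
  N.pool_argmax.clear();
  N.last_act.reset();
  N.par.clear();
  return grads;
}

// standalone padded cross-correlation, exported as a test oracle surface
// [[Rcpp::export]]
NumericVector conv3d_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dm = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  if (dm.size() != 4 || wd.size() != 5) stop("bad dims");
  const int nx = dm[0], ny = dm[1], nz = dm[2], Cin = dm[3];
  const int kz = wd[2], Cout = wd[4];
  if (wd[3] != Cin) stop("channel mismatch");
  const size_t nvox = (size_t)nx * ny * nz;
  fmat A(nvox, Cin);
  for (size_t i = 0; i < nvox * Cin; ++i) A[i] = (float)x[i];
  fmat W(wd[0] * wd[1] * kz * Cin, Cout);
  for (int i = 0; i < (int)W.n_elem; ++i) W[i] = (float)w[i];
  fvec bb(Cout);
  for (int i = 0; i < Cout; ++i) bb[i] = (float)b[i];
  fmat out = conv_forward(A, W, bb, nx, ny, nz, kz);
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(nx, ny, nz, Cout);
  return res;
}
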