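// 3D U-net regression model: hand-rolled forward and reverse-mode gradients.
//
// Performance-critical layout: every feature map lives on a grid padded by
// one voxel of zeros on all faces and is stored channels-last as an
// arma::fmat with one ROW per padded voxel and one COLUMN per channel
// (padded voxel index v = x + px*(y + py*z)). With that layout a 3x3x3
// stride-1 "same" convolution is 27 plain sgemm calls on row-shifted views
// of the input (the zero ring provides the padding), with no im2col
// gather. Stride-2 down-convolutions and kernel-2 stride-2 transposed
// convolutions act on 8x smaller volumes and use explicit gather/scatter.
// The ring is re-zeroed after every operation that disturbs it, in both
// the forward and the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

extern "C" {
void sgemm_(const char* transa, const char* transb, const int* m,
            const int* n, const int* k, const float* alpha, const float* a,
            const int* lda, const float* b, const int* ldb,
            const float* beta, float* c, const int* ldc);
}

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

struct Grid {
  int nx, ny, nz;          // logical (interior) dims
  int px, py, pz;          // padded dims (+2)
  Grid() : nx(0), ny(0), nz(0), px(0), py(0), pz(0) {}
  explicit Grid(int x, int y, int z)
      : nx(x), ny(y), nz(z), px(x + 2), py(y + 2), pz(z + 2) {}
  int nint() const { return nx * ny * nz; }
  int P() const { return px * py * pz; }
  Grid half() const { return Grid(nx / 2, ny / 2, nz / 2); }
  Grid twice() const { return Grid(nx * 2, ny * 2, nz * 2); }
};

// zero every ring (non-interior) row of X
static void zero_ring(fmat& X, const Grid& g) {
  for (size_t c = 0; c < X.n_cols; ++c) {
    float* p = X.colptr(c);
    for (int z = 0; z < g.pz; ++z) {
      const bool zb = (z == 0 || z == g.pz - 1);
      for (int y = 0; y < g.py; ++y) {
        float* row = p + (size_t)(z * g.py + y) * g.px;
        if (zb || y == 0 || y == g.py - 1) {
          std::memset(row, 0, g.px * sizeof(float));
        } else {
          row[0] = 0.0f;
          row[g.px - 1] = 0.0f;
        }
      }
    }
  }
}

// copy a (nint x C) compact block into / out of the padded layout
static fmat embed(const fmat& compact, const Grid& g) {
  fmat X(g.P(), compact.n_cols, arma::fill::zeros);
  for (size_t c = 0; c < compact.n_cols; ++c) {
    const float* src = compact.colptr(c);
    float* dst = X.colptr(c);
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        std::memcpy(dst + (size_t)((z + 1) * g.py + y + 1) * g.px + 1,
                    src + (size_t)(z * g.ny + y) * g.nx,
                    g.nx * sizeof(float));
  }
  return X;
}

static fmat extract(const fmat& X, const Grid& g) {
  fmat out(g.nint(), X.n_cols);
  for (size_t c = 0; c < X.n_cols; ++c) {
    const float* src = X.colptr(c);
    float* dst = out.colptr(c);
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        std::memcpy(dst + (size_t)(z * g.ny + y) * g.nx,
                    src + (size_t)((z + 1) * g.py + y + 1) * g.px + 1,
                    g.nx * sizeof(float));
  }
  return out;
}

// ---- stride-1 3x3x3 convolution via shifted GEMMs -----------------------
// weights W: fmat (Cin x 27*Cout); offset block o is columns
// [o*Cout, (o+1)*Cout), i.e. a (Cin x Cout) matrix with ldb = Cin.

static void conv3_fwd(const fmat& X, const Grid& g, const fmat& W,
                      const fvec& b, fmat& Y) {
  const int Cin = X.n_cols;
  const int Cout = W.n_cols / 27;
  const int P = g.P();
  Y.zeros(P, Cout);
  int o = 0;
  for (int kz = -1; kz <= 1; ++kz)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx, ++o) {
        const int delta = (kz * g.py + ky) * g.px + kx;
        const int v0 = std::max(0, -delta);
        const int v1 = P - std::max(0, delta);
        sgemm('N', 'N', v1 - v0, Cout, Cin, 1.0f,
              X.memptr() + v0 + delta, P,
              W.memptr() + (size_t)o * Cout * Cin, Cin, 1.0f,
              Y.memptr() + v0, P);
      }
  for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  zero_ring(Y, g);
}

// dY must have a zero ring; dX is allocated and gets a zero ring.
static void conv3_bwd(const fmat& X, const Grid& g, const fmat& W,
                      const fmat& dY, fmat& dX, fmat& dW, fvec& db) {
  const int Cin = X.n_cols;
  const int Cout = W.n_cols / 27;
  const int P = g.P();
  dX.zeros(P, Cin);
  int o = 0;
  for (int kz = -1; kz <= 1; ++kz)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx, ++o) {
        const int delta = (kz * g.py + ky) * g.px + kx;
        const int v0 = std::max(0, -delta);
        const int v1 = P - std::max(0, delta);
        const int M = v1 - v0;
        // dX[v+delta] += dY[v] * W_o^T
        sgemm('N', 'T', M, Cin, Cout, 1.0f, dY.memptr() + v0, P,
              W.memptr() + (size_t)o * Cout * Cin, Cin, 1.0f,
              dX.memptr() + v0 + delta, P);
        // dW_o += X[v+delta]^T * dY[v]
        sgemm('T', 'N', Cin, Cout, M, 1.0f, X.memptr() + v0 + delta, P,
              dY.memptr() + v0, P, 1.0f,
              dW.memptr() + (size_t)o * Cout * Cin, Cin);
      }
  db += arma::sum(dY, 0).t();
  zero_ring(dX, g);
}

// ---- stride-2 3x3x3 down-convolution (gathered im2col) ------------------
// weights: fmat (27*Cin x Cout)

static fmat down_gather(const fmat& X, const Grid& g, const Grid& go) {
  const int Cin = X.n_cols;
  fmat col(go.nint(), 27 * Cin);
  int o = 0;
  for (int kz = -1; kz <= 1; ++kz)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx, ++o)
        for (int c = 0; c < Cin; ++c) {
          const float* src = X.colptr(c);
          float* dst = col.colptr((size_t)o * Cin + c);
          size_t w = 0;
          for (int oz = 0; oz < go.nz; ++oz) {
            const int iz = 2 * oz + 1 + kz;
            for (int oy = 0; oy < go.ny; ++oy) {
              const int iy = 2 * oy + 1 + ky;
              const float* row = src + (size_t)(iz * g.py + iy) * g.px;
              for (int ox = 0; ox < go.nx; ++ox)
                dst[w++] = row[2 * ox + 1 + kx];
            }
          }
        }
  return col;
}

static void down_scatter_add(const fmat& dcol, const Grid& g, const Grid& go,
                             fmat& dX) {
  const int Cin = dX.n_cols;
  int o = 0;
  for (int kz = -1; kz <= 1; ++kz)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kx = -1; kx <= 1; ++kx, ++o)
        for (int c = 0; c < Cin; ++c) {
          float* dst = dX.colptr(c);
          const float* src = dcol.colptr((size_t)o * Cin + c);
          size_t w = 0;
          for (int oz = 0; oz < go.nz; ++oz) {
            const int iz = 2 * oz + 1 + kz;
            for (int oy = 0; oy < go.ny; ++oy) {
              const int iy = 2 * oy + 1 + ky;
              float* row = dst + (size_t)(iz * g.py + iy) * g.px;
              for (int ox = 0; ox < go.nx; ++ox)
                row[2 * ox + 1 + kx] += src[w++];
            }
          }
        }
  zero_ring(dX, g);
}

// ---- kernel-2 stride-2 transposed convolution ---------------------------
// weights: fmat (Cin x 8*Cout); input on small grid, output on doubled grid

static void up_scatter(const fmat& tmp, const Grid& gs, const Grid& gb,
                       fmat& Y) {
  const int Cout = tmp.n_cols / 8;
  int o = 0;
  for (int kz = 0; kz < 2; ++kz)
    for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx, ++o)
        for (int c = 0; c < Cout; ++c) {
          const float* src = tmp.colptr((size_t)o * Cout + c);
          float* dst = Y.colptr(c);
          size_t w = 0;
          for (int iz = 0; iz < gs.nz; ++iz) {
            const int oz = 2 * iz + kz + 1;
            for (int iy = 0; iy < gs.ny; ++iy) {
              const int oy = 2 * iy + ky + 1;
              float* row = dst + (size_t)(oz * gb.py + oy) * gb.px;
              for (int ix = 0; ix < gs.nx; ++ix)
                row[2 * ix + kx + 1] = src[w++];
            }
          }
        }
}

static void up_gather(const fmat& dY, const Grid& gs, const Grid& gb,
                      fmat& dtmp) {
  const int Cout = dtmp.n_cols / 8;
  int o = 0;
  for (int kz = 0; kz < 2; ++kz)
    for (int ky = 0; ky < 2; ++ky)
      for (int kx = 0; kx < 2; ++kx, ++o)
        for (int c = 0; c < Cout; ++c) {
          float* dst = dtmp.colptr((size_t)o * Cout + c);
          const float* src = dY.colptr(c);
          size_t w = 0;
          for (int iz = 0; iz < gs.nz; ++iz) {
            const int oz = 2 * iz + kz + 1;
            for (int iy = 0; iy < gs.ny; ++iy) {
              const int oy = 2 * iy + ky + 1;
              const float* row = src + (size_t)(oz * gb.py + oy) * gb.px;
              for (int ix = 0; ix < gs.nx; ++ix)
                dst[w++] = row[2 * ix + kx + 1];
            }
          }
        }
}

// ---- group normalization + PReLU (channels-last) ------------------------

static const float GN_EPS = 1e-5f;

// statistics over the interior only; the zero ring contributes nothing to
// the sums, so whole-column accumulations divided by the interior count
// are exact.
static void gn_prelu_fwd(const fmat& Z, const Grid& g, int G,
                         const fvec& gamma, const fvec& beta, const fvec& a,
                         fmat& H, fmat& Y, fvec& mu, fvec& inv) {
  const int C = Z.n_cols;
  const int Cg = C / G;
  const double N = (double)Cg * g.nint();
  mu.set_size(G);
  inv.set_size(G);
  H.set_size(Z.n_rows, C);
  Y.set_size(Z.n_rows, C);
  for (int grp = 0; grp < G; ++grp) {
    double s = 0, s2 = 0;
    for (int c = grp * Cg; c < (grp + 1) * Cg; ++c) {
      s += arma::accu(Z.col(c));
      s2 += arma::dot(Z.col(c), Z.col(c));
    }
    const float m = (float)(s / N);
    const float var = (float)(s2 / N - (double)m * m);
    const float iv = 1.0f / std::sqrt(std::max(var, 0.0f) + GN_EPS);
    mu[grp] = m;
    inv[grp] = iv;
    for (int c = grp * Cg; c < (grp + 1) * Cg; ++c) {
      const float sc = iv * gamma[c];
      const float sh = beta[c] - m * sc;
      const float ac = a[c];
      H.col(c) = Z.col(c) * sc + sh;
      // prelu(h) = (1+a)/2 * h + (1-a)/2 * |h|
      Y.col(c) = 0.5f * (1.0f + ac) * H.col(c) +
                 0.5f * (1.0f - ac) * arma::abs(H.col(c));
    }
  }
  zero_ring(H, g);  // ring of H is (0 - mu)*scale + beta: not zero
  zero_ring(Y, g);
}

// dY must have a zero ring; dZ gets one.
static void gn_prelu_bwd(const fmat& Z, const fmat& H, const Grid& g, int G,
                         const fvec& gamma, const fvec& a, const fvec& mu,
                         const fvec& inv, const fmat& dY, fmat& dZ,
                         fvec& dgamma, fvec& dbeta, fvec& da) {
  const int C = Z.n_cols;
  const int Cg = C / G;
  const double N = (double)Cg * g.nint();
  dZ.set_size(Z.n_rows, C);
  fmat dH(Z.n_rows, Cg);   // post-PReLU gradients, one column per channel
  fmat XH(Z.n_rows, Cg);   // normalized activations of the group
  for (int grp = 0; grp < G; ++grp) {
    const float iv = inv[grp];
    const float m = mu[grp];
    double m1 = 0, m2 = 0;
    for (int j = 0; j < Cg; ++j) {
      const int c = grp * Cg + j;
      const float ac = a[c];
      // d(prelu)/dh = (1+a)/2 + (1-a)/2 * sign(h); for h <= 0 the slope
      // gradient accumulates dy * h (H caches the PReLU input);
      // min(h, 0) = (h - |h|)/2
      dH.col(j) = 0.5f * (1.0f + ac) * dY.col(c) +
                  0.5f * (1.0f - ac) * (dY.col(c) % arma::sign(H.col(c)));
      da[c] += 0.5f * (arma::dot(dY.col(c), H.col(c)) -
                       arma::dot(dY.col(c), arma::abs(H.col(c))));
      XH.col(j) = (Z.col(c) - m) * iv;
      const float sg = arma::dot(dH.col(j), XH.col(j));
      const float sb = arma::accu(dH.col(j));
      // ring rows of dY are zero, so these sums cover the interior only
      dgamma[c] += sg;
      dbeta[c] += sb;
      m1 += (double)gamma[c] * sb;
      m2 += (double)gamma[c] * sg;
    }
    m1 /= N;
    m2 /= N;
    for (int j = 0; j < Cg; ++j) {
      const int c = grp * Cg + j;
      dZ.col(c) = iv * (dH.col(j) * gamma[c] - (float)m1 -
                        XH.col(j) * (float)m2);
    }
  }
  zero_ring(dZ, g);
}

// ---- configuration and parameters ---------------------------------------

struct NetCfg {
  int L, nconv, G, k;
  std::vector<int> f;
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.L = as<int>(cfg["n_levels"]);
  c.nconv = as<int>(cfg["convs_per_block"]);
  c.G = as<int>(cfg["norm_groups"]);
  c.k = as<int>(cfg["kernel_size"]);
  if (c.k != 3) stop("this build supports kernel_size = 3");
  IntegerVector f = cfg["base_filters"];
  c.f.assign(f.begin(), f.end());
  if ((int)c.f.size() != c.L) stop("base_filters length must equal n_levels");
  for (int fi : c.f)
    if (fi % c.G != 0)
      stop("every channel count must be divisible by norm_groups");
  return c;
}

// Parameter walk: for each conv unit in construction order emit
// W, b, gamma, beta, a. Shapes (rows, cols, fan_in):
//   stride-1 conv:  W (Cin  x 27*Cout), fan_in = 27*Cin
//   down conv:      W (27*Cin x Cout),  fan_in = 27*Cin
//   up (transposed) W (Cin  x 8*Cout),  fan_in = Cin
//   final 1x1x1:    W (f1 x 1), b (1)
// [[Rcpp::export]]
List cpp_param_shapes(List cfg) {
  NetCfg c = parse_cfg(cfg);
  std::vector<std::string> names;
  std::vector<IntegerVector> shapes;
  auto unit = [&](const std::string& base, int wr, int wc, int cout,
                  int fan_in) {
    names.push_back(base + "_W");
    shapes.push_back(IntegerVector::create(wr, wc, fan_in));
    const char* tails[] = {"_b", "_gamma", "_beta", "_a"};
    for (const char* t : tails) {
      names.push_back(base + t);
      shapes.push_back(IntegerVector::create(cout, 1, 0));
    }
  };
  for (int i = 0; i < c.L; ++i) {
    for (int j = 0; j < c.nconv; ++j) {
      int cin = (i == 0 && j == 0) ? 1 : c.f[i];
      unit("enc" + std::to_string(i + 1) + "_conv" + std::to_string(j + 1),
           cin, 27 * c.f[i], c.f[i], 27 * cin);
    }
    if (i < c.L - 1)
      unit("down" + std::to_string(i + 1), 27 * c.f[i], c.f[i + 1],
           c.f[i + 1], 27 * c.f[i]);
  }
  for (int i = c.L - 2; i >= 0; --i) {
    unit("up" + std::to_string(i + 1), c.f[i + 1], 8 * c.f[i], c.f[i],
         c.f[i + 1]);
    for (int j = 0; j < c.nconv; ++j) {
      int cin = (j == 0) ? 2 * c.f[i] : c.f[i];
      unit("dec" + std::to_string(i + 1) + "_conv" + std::to_string(j + 1),
           cin, 27 * c.f[i], c.f[i], 27 * cin);
    }
  }
  names.push_back("final_W");
  shapes.push_back(IntegerVector::create(c.f[0], 1, c.f[0]));
  names.push_back("final_b");
  shapes.push_back(IntegerVector::create(1, 1, 0));
  List res(shapes.size());
  for (size_t i = 0; i < shapes.size(); ++i) res[i] = shapes[i];
  res.names() = wrap(names);
  return res;
}

static std::vector<fmat> read_params(const List& params) {
  std::vector<fmat> P;
  P.reserve(params.size());
  for (int i = 0; i < params.size(); ++i) {
    NumericVector v = params[i];
    int r = v.size(), cc = 1;
    if (v.hasAttribute("dim")) {
      IntegerVector dd = v.attr("dim");
      if (dd.size() == 2) {
        r = dd[0];
        cc = dd[1];
      }
    }
    fmat M(r, cc);
    for (int j = 0; j < r * cc; ++j) M[j] = (float)v[j];
    P.push_back(std::move(M));
  }
  return P;
}

static std::vector<fmat> zeros_like(const std::vector<fmat>& P) {
  std::vector<fmat> G;
  G.reserve(P.size());
  for (const fmat& m : P)
    G.emplace_back(m.n_rows, m.n_cols, arma::fill::zeros);
  return G;
}

struct Layout {
  std::vector<std::vector<int>> enc, dec;
  std::vector<int> down, up;
  int final_W, final_b;
};

static Layout make_layout(const NetCfg& c) {
  Layout lay;
  int idx = 0;
  lay.enc.resize(c.L);
  lay.down.resize(c.L - 1);
  lay.up.resize(c.L - 1);
  lay.dec.resize(c.L - 1);
  for (int i = 0; i < c.L; ++i) {
    for (int j = 0; j < c.nconv; ++j) {
      lay.enc[i].push_back(idx);
      idx += 5;
    }
    if (i < c.L - 1) {
      lay.down[i] = idx;
      idx += 5;
    }
  }
  for (int i = c.L - 2; i >= 0; --i) {
    lay.up[i] = idx;
    idx += 5;
    for (int j = 0; j < c.nconv; ++j) {
      lay.dec[i].push_back(idx);
      idx += 5;
    }
  }
  lay.final_W = idx;
  lay.final_b = idx + 1;
  return lay;
}

// ---- composite layer: conv (any flavor) + groupnorm + prelu -------------

struct UnitCache {
  fmat x;        // layer input (padded, channels-last)
  fmat z;        // pre-normalization (padded)
  fmat h;        // pre-activation (padded)
  fvec mu, inv;
  Grid gin, gout;
};

enum ConvKind { CONV3, DOWN, UP };

static fmat unit_fwd(const std::vector<fmat>& P, int bi, const NetCfg& c,
                     ConvKind kind, const fmat& x, const Grid& gin,
                     Grid& gout, UnitCache* cache) {
  const fmat& W = P[bi];
  const fvec b(P[bi + 1].memptr(), P[bi + 1].n_rows);
  const fvec gamma(P[bi + 2].memptr(), P[bi + 2].n_rows);
  const fvec beta(P[bi + 3].memptr(), P[bi + 3].n_rows);
  const fvec a(P[bi + 4].memptr(), P[bi + 4].n_rows);
  fmat z;
  if (kind == CONV3) {
    gout = gin;
    conv3_fwd(x, gin, W, b, z);
  } else if (kind == DOWN) {
    gout = gin.half();
    const int Cout = W.n_cols;
    fmat col = down_gather(x, gin, gout);
    fmat zc(gout.nint(), Cout);
    sgemm('N', 'N', gout.nint(), Cout, W.n_rows, 1.0f, col.memptr(),
          gout.nint(), W.memptr(), W.n_rows, 0.0f, zc.memptr(), gout.nint());
    zc.each_row() += b.t();
    z = embed(zc, gout);
  } else {  // UP
    gout = gin.twice();
    const int Cout = W.n_cols / 8;
    fmat xs = extract(x, gin);
    fmat tmp(gin.nint(), W.n_cols);
    sgemm('N', 'N', gin.nint(), W.n_cols, W.n_rows, 1.0f, xs.memptr(),
          gin.nint(), W.memptr(), W.n_rows, 0.0f, tmp.memptr(), gin.nint());
    z.zeros(gout.P(), Cout);
    up_scatter(tmp, gin, gout, z);
    for (int cc = 0; cc < Cout; ++cc) z.col(cc) += b[cc];
    zero_ring(z, gout);
  }
  fmat h, y;
  fvec mu, inv;
  gn_prelu_fwd(z, gout, c.G, gamma, beta, a, h, y, mu, inv);
  if (cache) {
    cache->x = x;
    cache->z = std::move(z);
    cache->h = std::move(h);
    cache->mu = std::move(mu);
    cache->inv = std::move(inv);
    cache->gin = gin;
    cache->gout = gout;
  }
  return y;
}

static fmat unit_bwd(const std::vector<fmat>& P, int bi, const NetCfg& c,
                     ConvKind kind, const UnitCache& cc, const fmat& dy,
                     std::vector<fmat>& Gr) {
  const fmat& W = P[bi];
  const fvec gamma(P[bi + 2].memptr(), P[bi + 2].n_rows);
  const fvec a(P[bi + 4].memptr(), P[bi + 4].n_rows);
  fvec dgamma(Gr[bi + 2].memptr(), Gr[bi + 2].n_rows, false, true);
  fvec dbeta(Gr[bi + 3].memptr(), Gr[bi + 3].n_rows, false, true);
  fvec da(Gr[bi + 4].memptr(), Gr[bi + 4].n_rows, false, true);
  fmat dz;
  gn_prelu_bwd(cc.z, cc.h, cc.gout, c.G, gamma, a, cc.mu, cc.inv, dy, dz,
               dgamma, dbeta, da);
  fvec db(Gr[bi + 1].memptr(), Gr[bi + 1].n_rows, false, true);
  fmat dx;
  if (kind == CONV3) {
    conv3_bwd(cc.x, cc.gin, W, dz, dx, Gr[bi], db);
  } else if (kind == DOWN) {
    fmat dzc = extract(dz, cc.gout);
    db += arma::sum(dzc, 0).t();
    const int Cout = W.n_cols;
    fmat col = down_gather(cc.x, cc.gin, cc.gout);
    // dW += col^T * dzc ; dcol = dzc * W^T
    sgemm('T', 'N', W.n_rows, Cout, cc.gout.nint(), 1.0f, col.memptr(),
          cc.gout.nint(), dzc.memptr(), cc.gout.nint(), 1.0f,
          Gr[bi].memptr(), W.n_rows);
    fmat dcol(cc.gout.nint(), W.n_rows);
    sgemm('N', 'T', cc.gout.nint(), W.n_rows, Cout, 1.0f, dzc.memptr(),
          cc.gout.nint(), W.memptr(), W.n_rows, 0.0f, dcol.memptr(),
          cc.gout.nint());
    dx.zeros(cc.gin.P(), cc.x.n_cols);
    down_scatter_add(dcol, cc.gin, cc.gout, dx);
  } else {  // UP
    db += arma::sum(dz, 0).t();
    fmat dtmp(cc.gin.nint(), W.n_cols);
    up_gather(dz, cc.gin, cc.gout, dtmp);
    fmat xs = extract(cc.x, cc.gin);
    sgemm('T', 'N', W.n_rows, W.n_cols, cc.gin.nint(), 1.0f, xs.memptr(),
          cc.gin.nint(), dtmp.memptr(), cc.gin.nint(), 1.0f,
          Gr[bi].memptr(), W.n_rows);
    fmat dxs(cc.gin.nint(), W.n_rows);
    sgemm('N', 'T', cc.gin.nint(), W.n_rows, W.n_cols, 1.0f, dtmp.memptr(),
          cc.gin.nint(), W.memptr(), W.n_rows, 0.0f, dxs.memptr(),
          cc.gin.nint());
    dx = embed(dxs, cc.gin);
  }
  return dx;
}

// ---- whole network ------------------------------------------------------

struct FwdState {
  std::vector<std::vector<UnitCache>> enc, dec;
  std::vector<UnitCache> down, up;
  std::vector<fmat> skip;
  fmat pre_final;
  Grid gfinal;
};

static fmat net_fwd(const std::vector<fmat>& P, const NetCfg& c,
                    const Layout& lay, const fmat& x0, const Grid& g0,
                    FwdState* st) {
  if (st) {
    st->enc.resize(c.L);
    st->dec.resize(c.L - 1);
    st->down.resize(c.L - 1);
    st->up.resize(c.L - 1);
    st->skip.resize(c.L - 1);
    for (int i = 0; i < c.L; ++i) st->enc[i].resize(c.nconv);
    for (int i = 0; i < c.L - 1; ++i) st->dec[i].resize(c.nconv);
  }
  fmat cur = x0;
  Grid g = g0, gn;
  std::vector<fmat> skip(c.L - 1);
  std::vector<Grid> skip_g(c.L - 1);
  for (int i = 0; i < c.L; ++i) {
    for (int j = 0; j < c.nconv; ++j) {
      cur = unit_fwd(P, lay.enc[i][j], c, CONV3, cur, g, gn,
                     st ? &st->enc[i][j] : nullptr);
      g = gn;
    }
    if (i < c.L - 1) {
      skip[i] = cur;
      skip_g[i] = g;
      if (st) st->skip[i] = cur;
      cur = unit_fwd(P, lay.down[i], c, DOWN, cur, g, gn,
                     st ? &st->down[i] : nullptr);
      g = gn;
    }
  }
  for (int i = c.L - 2; i >= 0; --i) {
    cur = unit_fwd(P, lay.up[i], c, UP, cur, g, gn,
                   st ? &st->up[i] : nullptr);
    g = gn;
    if (g.nx != skip_g[i].nx || g.ny != skip_g[i].ny || g.nz != skip_g[i].nz)
      stop("internal: decoder/skip shape mismatch");
    cur = arma::join_rows(cur, skip[i]);  // [upsampled | skip] channels
    for (int j = 0; j < c.nconv; ++j) {
      cur = unit_fwd(P, lay.dec[i][j], c, CONV3, cur, g, gn,
                     st ? &st->dec[i][j] : nullptr);
      g = gn;
    }
  }
  if (st) {
    st->pre_final = cur;
    st->gfinal = g;
  }
  const fmat& Wf = P[lay.final_W];
  fmat out(cur.n_rows, 1);
  sgemm('N', 'N', cur.n_rows, 1, Wf.n_rows, 1.0f, cur.memptr(), cur.n_rows,
        Wf.memptr(), Wf.n_rows, 0.0f, out.memptr(), cur.n_rows);
  out += P[lay.final_b](0, 0);
  zero_ring(out, g);
  return out;  // padded (P x 1)
}

static void net_bwd(const std::vector<fmat>& P, const NetCfg& c,
                    const Layout& lay, const FwdState& st, const fmat& dout,
                    std::vector<fmat>& Gr) {
  // final 1x1x1 conv (dout has a zero ring)
  const fmat& Wf = P[lay.final_W];
  sgemm('T', 'N', Wf.n_rows, 1, st.pre_final.n_rows, 1.0f,
        st.pre_final.memptr(), st.pre_final.n_rows, dout.memptr(),
        dout.n_rows, 1.0f, Gr[lay.final_W].memptr(), Wf.n_rows);
  Gr[lay.final_b](0, 0) += arma::accu(dout);
  fmat dcur(dout.n_rows, Wf.n_rows);
  sgemm('N', 'T', dout.n_rows, Wf.n_rows, 1, 1.0f, dout.memptr(),
        dout.n_rows, Wf.memptr(), Wf.n_rows, 0.0f, dcur.memptr(),
        dout.n_rows);
  zero_ring(dcur, st.gfinal);
  std::vector<fmat> dskip(c.L - 1);
  for (int i = 0; i <= c.L - 2; ++i) {
    for (int j = c.nconv - 1; j >= 0; --j)
      dcur = unit_bwd(P, lay.dec[i][j], c, CONV3, st.dec[i][j], dcur, Gr);
    const int cup = c.f[i];
    fmat dup = dcur.cols(0, cup - 1);
    dskip[i] = dcur.cols(cup, dcur.n_cols - 1);
    dcur = unit_bwd(P, lay.up[i], c, UP, st.up[i], dup, Gr);
  }
  for (int i = c.L - 1; i >= 0; --i) {
    if (i < c.L - 1) {
      dcur = unit_bwd(P, lay.down[i], c, DOWN, st.down[i], dcur, Gr);
      dcur += dskip[i];
    }
    for (int j = c.nconv - 1; j >= 0; --j)
      dcur = unit_bwd(P, lay.enc[i][j], c, CONV3, st.enc[i][j], dcur, Gr);
  }
}

// ---- R entry points -----------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List params, List cfg, NumericVector x) {
  NetCfg c = parse_cfg(cfg);
  Layout lay = make_layout(c);
  std::vector<fmat> P = read_params(params);
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("input must be a 4-d array (nx, ny, nz, batch)");
  Grid g(dd[0], dd[1], dd[2]);
  const int B = dd[3];
  const int V = g.nint();
  NumericVector out(x.size());
  out.attr("dim") = dd;
  for (int b = 0; b < B; ++b) {
    fmat xc(V, 1);
    for (int v = 0; v < V; ++v) xc(v, 0) = (float)x[(R_xlen_t)b * V + v];
    fmat yb = extract(net_fwd(P, c, lay, embed(xc, g), g, nullptr), g);
    for (int v = 0; v < V; ++v) out[(R_xlen_t)b * V + v] = (double)yb(v, 0);
  }
  return out;
}

// Mean-absolute-error loss and parameter gradients over a batch.
// [[Rcpp::export]]
List cpp_unet_loss_grad(List params, List cfg, NumericVector x,
                        NumericVector target,
                        std::string loss_type = "mae") {
  const bool mse = (loss_type == "mse");
  if (!mse && loss_type != "mae") stop("loss_type must be 'mae' or 'mse'");
  NetCfg c = parse_cfg(cfg);
  Layout lay = make_layout(c);
  std::vector<fmat> P = read_params(params);
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("input must be a 4-d array (nx, ny, nz, batch)");
  if (x.size() != target.size()) stop("input/target size mismatch");
  Grid g(dd[0], dd[1], dd[2]);
  const int B = dd[3];
  const int V = g.nint();
  std::vector<fmat> Gr = zeros_like(P);
  double loss = 0.0;
  const float gscale = 1.0f / ((float)B * (float)V);
  for (int b = 0; b < B; ++b) {
    fmat xc(V, 1), tc(V, 1);
    for (int v = 0; v < V; ++v) {
      xc(v, 0) = (float)x[(R_xlen_t)b * V + v];
      tc(v, 0) = (float)target[(R_xlen_t)b * V + v];
    }
    FwdState st;
    fmat pred = net_fwd(P, c, lay, embed(xc, g), g, &st);
    fmat diff = pred - embed(tc, g);  // ring is zero on both sides
    fmat dy(diff.n_rows, 1);
    if (mse) {
      loss += arma::dot(diff, diff);
      dy = diff * (2.0f * gscale);
    } else {
      loss += arma::accu(arma::abs(diff));
      const size_t n = diff.n_rows;
      for (size_t v = 0; v < n; ++v) {
        const float dv = diff(v, 0);
        dy(v, 0) = dv > 0 ? gscale : (dv < 0 ? -gscale : 0.0f);
      }
    }
    net_bwd(P, c, lay, st, dy, Gr);
  }
  loss /= (double)B * V;
  List grads(Gr.size());
  for (size_t i = 0; i < Gr.size(); ++i) {
    NumericVector gv(Gr[i].n_elem);
    for (size_t j = 0; j < Gr[i].n_elem; ++j) gv[j] = (double)Gr[i][j];
    gv.attr("dim") =
        IntegerVector::create((int)Gr[i].n_rows, (int)Gr[i].n_cols);
    grads[i] = gv;
  }
  grads.names() = params.names();
  return List::create(Named("loss") = loss, Named("grads") = grads);
}

// ---- exact squared Euclidean distance transform -------------------------
// (Felzenszwalb-Huttenlocher), used for cosine mask edges. Input: logical
// 3-d array (TRUE = foreground); output: squared distance (voxels^2) to
// the nearest FALSE voxel (0 for background voxels).

static void edt_1d(const std::vector<double>& f, std::vector<double>& dout,
                   std::vector<int>& v, std::vector<double>& zbuf) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  zbuf[0] = -1e30;
  zbuf[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    const double dq = q - v[k];
    dout[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask) {
  IntegerVector dd = mask.attr("dim");
  if (dd.size() != 3) stop("mask must be a 3-d array");
  const int nx = dd[0], ny = dd[1], nz = dd[2];
  std::vector<double> D((size_t)nx * ny * nz);
  for (size_t i = 0; i < D.size(); ++i) D[i] = mask[i] ? 1e30 : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dout(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const size_t base = (size_t)(z * ny + y) * nx;
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      edt_1d(std::vector<double>(f.begin(), f.begin() + nx), dout, v, zbuf);
      for (int i = 0; i < nx; ++i) D[base + i] = dout[i];
    }
  for (int z = 0; z < nz; ++z)
    for (int xq = 0; xq < nx; ++xq) {
      for (int i = 0; i < ny; ++i) f[i] = D[(size_t)(z * ny + i) * nx + xq];
      edt_1d(std::vector<double>(f.begin(), f.begin() + ny), dout, v, zbuf);
      for (int i = 0; i < ny; ++i) D[(size_t)(z * ny + i) * nx + xq] = dout[i];
    }
  for (int y = 0; y < ny; ++y)
    for (int xq = 0; xq < nx; ++xq) {
      for (int i = 0; i < nz; ++i) f[i] = D[(size_t)(i * ny + y) * nx + xq];
      edt_1d(std::vector<double>(f.begin(), f.begin() + nz), dout, v, zbuf);
      for (int i = 0; i < nz; ++i) D[(size_t)(i * ny + y) * nx + xq] = dout[i];
    }
  NumericVector out(D.size());
  for (size_t i = 0; i < D.size(); ++i) out[i] = D[i];
  out.attr("dim") = dd;
  return out;
}
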