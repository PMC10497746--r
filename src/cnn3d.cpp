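// Multi-scale 3D convolutional network engine for 5x5xK hyperspectral blocks.
//
// Everything is single precision and single threaded: blocks are tiny, GEMM
// via im2col dominates, and one thread keeps training bit-reproducible for a
// fixed seed. Weight layout for a conv layer is (out_ch, kvol*in_ch) with
// column index t*C + c (tap-major), matching the tap-major im2col below so
// the gather is a straight memcpy of C floats per tap.
//
// Voxel index convention: v = d + D*(h + H*w)  (spectral depth d fastest).

#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef arma::fmat FMat;
typedef arma::Mat<int> IMat;

struct ConvShape {
  int kd, kh, kw;      // kernel extents, depth first
  int C;               // input channels
  int F;               // output channels (filters)
};

struct ModuleDims {
  int D, H, W;         // input dims of the module
};

// im2col index table: (kvol x V) of source voxel index, -1 = zero padding
static IMat build_idx(int D, int H, int W, int kd, int kh, int kw) {
  const int pd = (kd - 1) / 2, ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int V = D * H * W, kvol = kd * kh * kw;
  IMat idx(kvol, V);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        const int v = d + D * (h + H * w);
        for (int tw = 0; tw < kw; ++tw)
          for (int th = 0; th < kh; ++th)
            for (int td = 0; td < kd; ++td) {
              const int t = td + kd * (th + kh * tw);
              const int sd = d + td - pd, sh = h + th - ph, sw = w + tw - pw;
              idx(t, v) =
                (sd >= 0 && sd < D && sh >= 0 && sh < H && sw >= 0 && sw < W)
                  ? sd + D * (sh + H * sw) : -1;
            }
      }
  return idx;
}

// gather A (C x V*N) into Cols (kvol*C x V*N)
static void im2col(const FMat& A, const IMat& idx, int C, int V, int N,
                   FMat& Cols) {
  const int kvol = idx.n_rows;
  Cols.set_size(kvol * C, (size_t)V * N);
  for (int n = 0; n < N; ++n) {
    const float* Abase = A.colptr((size_t)n * V);
    for (int v = 0; v < V; ++v) {
      float* colp = Cols.colptr((size_t)v + (size_t)n * V);
      for (int t = 0; t < kvol; ++t) {
        const int src = idx(t, v);
        if (src >= 0)
          std::memcpy(colp + (size_t)t * C, Abase + (size_t)src * C,
                      C * sizeof(float));
        else
          std::memset(colp + (size_t)t * C, 0, C * sizeof(float));
      }
    }
  }
}

// scatter-add dCols back into dA (transpose of im2col)
static void col2im(const FMat& dCols, const IMat& idx, int C, int V, int N,
                   FMat& dA) {
  const int kvol = idx.n_rows;
  for (int n = 0; n < N; ++n) {
    float* Abase = dA.colptr((size_t)n * V);
    for (int v = 0; v < V; ++v) {
      const float* colp = dCols.colptr((size_t)v + (size_t)n * V);
      for (int t = 0; t < kvol; ++t) {
        const int src = idx(t, v);
        if (src < 0) continue;
        float* dst = Abase + (size_t)src * C;
        const float* sp = colp + (size_t)t * C;
        for (int c = 0; c < C; ++c) dst[c] += sp[c];
      }
    }
  }
}

// spectral max pooling, extent 2 stride 2 along d; drops a trailing odd slice
static void pool_forward(const FMat& A, int C, int D, int H, int W, int N,
                         FMat& Y, arma::Mat<unsigned char>& argmax) {
  const int D2 = D / 2, V = D * H * W, V2 = D2 * H * W;
  Y.set_size(C, (size_t)V2 * N);
  argmax.set_size(C, (size_t)V2 * N);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d2 = 0; d2 < D2; ++d2) {
          const size_t v1 = 2 * d2 + (size_t)D * (h + H * w) + (size_t)n * V;
          const size_t vo = d2 + (size_t)D2 * (h + H * w) + (size_t)n * V2;
          const float* a1 = A.colptr(v1);
          const float* a2 = A.colptr(v1 + 1);
          float* y = Y.colptr(vo);
          unsigned char* am = argmax.colptr(vo);
          for (int c = 0; c < C; ++c) {
            if (a1[c] >= a2[c]) { y[c] = a1[c]; am[c] = 0; }
            else               { y[c] = a2[c]; am[c] = 1; }
          }
        }
}

static void pool_backward(const FMat& dY, const arma::Mat<unsigned char>& argmax,
                          int C, int D, int H, int W, int N, FMat& dA) {
  const int D2 = D / 2, V = D * H * W, V2 = D2 * H * W;
  dA.zeros(C, (size_t)V * N);
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        for (int d2 = 0; d2 < D2; ++d2) {
          const size_t v1 = 2 * d2 + (size_t)D * (h + H * w) + (size_t)n * V;
          const size_t vo = d2 + (size_t)D2 * (h + H * w) + (size_t)n * V2;
          const float* g = dY.colptr(vo);
          const unsigned char* am = argmax.colptr(vo);
          float* d1 = dA.colptr(v1);
          float* d2p = dA.colptr(v1 + 1);
          for (int c = 0; c < C; ++c) {
            if (am[c]) d2p[c] += g[c]; else d1[c] += g[c];
          }
        }
}

struct Net {
  int n_mod, n_branch;
  std::vector<ConvShape> shapes;        // n_mod * n_branch, branch fastest
  std::vector<FMat> Wc;                 // conv weights
  std::vector<arma::fvec> bc;           // conv biases
  FMat W1, W2;                          // fully connected
  arma::fvec b1, b2;
  std::vector<int> filters;
  std::vector<int> pool_after;          // 0/1 per module
  int D0, H0, W0, fc_width, n_classes;

  std::vector<ModuleDims> dims;         // input dims per module
  int D_out;                            // depth after last module (+pool)
  std::vector<IMat> idx;                // im2col tables, same order as shapes

  void configure() {
    dims.clear(); idx.clear();
    int D = D0;
    int C = 1;
    for (int m = 0; m < n_mod; ++m) {
      ModuleDims md; md.D = D; md.H = H0; md.W = W0;
      dims.push_back(md);
      for (int b = 0; b < n_branch; ++b) {
        ConvShape& s = shapes[m * n_branch + b];
        s.C = C;
        idx.push_back(build_idx(D, H0, W0, s.kd, s.kh, s.kw));
      }
      C = n_branch * filters[m];
      if (pool_after[m] && D >= 2) D /= 2;
    }
    D_out = D;
  }

  int flat_dim() const {
    return n_branch * filters[n_mod - 1] * D_out * H0 * W0;
  }

  std::vector<FMat*> params() {
    std::vector<FMat*> p;
    for (size_t i = 0; i < Wc.size(); ++i) p.push_back(&Wc[i]);
    p.push_back(&W1); p.push_back(&W2);
    return p;
  }
  std::vector<arma::fvec*> vec_params() {
    std::vector<arma::fvec*> p;
    for (size_t i = 0; i < bc.size(); ++i) p.push_back(&bc[i]);
    p.push_back(&b1); p.push_back(&b2);
    return p;
  }
};

// cache of everything the backward pass needs
struct FwdCache {
  std::vector<FMat> act;                       // post-ReLU concat per module
  std::vector<FMat> pooled;                    // post-pool per module (if any)
  std::vector<arma::Mat<unsigned char> > amx;  // pool argmax per module
  FMat H1;                                     // post-ReLU fc1
  FMat P;                                      // softmax probabilities
};

static FMat net_forward(Net& net, const FMat& X, int N, FwdCache* cache) {
  FMat A = X;  // (C=1, V0*N)
  if (cache) {
    cache->act.resize(net.n_mod);
    cache->pooled.resize(net.n_mod);
    cache->amx.resize(net.n_mod);
  }
  for (int m = 0; m < net.n_mod; ++m) {
    const ModuleDims& md = net.dims[m];
    const int V = md.D * md.H * md.W;
    const int C = net.shapes[m * net.n_branch].C;
    const int Cout = net.n_branch * net.filters[m];
    FMat Y(Cout, (size_t)V * N);
    int off = 0;
    FMat Cols;
    for (int b = 0; b < net.n_branch; ++b) {
      const int li = m * net.n_branch + b;
      im2col(A, net.idx[li], C, V, N, Cols);
      FMat Yb = net.Wc[li] * Cols;
      Yb.each_col() += net.bc[li];
      Y.rows(off, off + net.filters[m] - 1) = Yb;
      off += net.filters[m];
    }
    Y.transform([](float x) { return x > 0.0f ? x : 0.0f; });  // ReLU
    if (cache) cache->act[m] = Y;
    if (net.pool_after[m] && md.D >= 2) {
      FMat Yp;
      arma::Mat<unsigned char> am;
      pool_forward(Y, Cout, md.D, md.H, md.W, N, Yp, am);
      if (cache) { cache->pooled[m] = Yp; cache->amx[m] = am; }
      A = Yp;
    } else {
      A = Y;
    }
  }
  // flatten: columns of one sample are contiguous in memory
  const int FD = net.flat_dim();
  FMat Fl(A.memptr(), FD, N, false, true);
  FMat Z1 = net.W1 * Fl;
  Z1.each_col() += net.b1;
  Z1.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  FMat Z2 = net.W2 * Z1;
  Z2.each_col() += net.b2;
  // softmax
  FMat P = Z2;
  for (int n = 0; n < N; ++n) {
    arma::fvec col = P.col(n);
    col -= col.max();
    col = arma::exp(col);
    P.col(n) = col / arma::accu(col);
  }
  if (cache) { cache->H1 = Z1; cache->P = P; }
  return P;
}

// backward pass; fills grads (same ordering as net.params()/vec_params())
static void net_backward(Net& net, const FMat& X, const arma::ivec& y, int N,
                         FwdCache& cache,
                         std::vector<FMat>& gW, std::vector<arma::fvec>& gb,
                         FMat& gW1, FMat& gW2, arma::fvec& gb1,
                         arma::fvec& gb2) {
  // softmax + CE gradient
  FMat dZ2 = cache.P;
  for (int n = 0; n < N; ++n) dZ2(y[n], n) -= 1.0f;
  dZ2 /= (float)N;
  gW2 = dZ2 * cache.H1.t();
  gb2 = arma::sum(dZ2, 1);
  FMat dH1 = net.W2.t() * dZ2;
  dH1 %= arma::conv_to<FMat>::from(cache.H1 > 0.0f);
  // recompute flattened input of fc1 (last module output)
  const int mL = net.n_mod - 1;
  const ModuleDims& mdL = net.dims[mL];
  FMat& Alast = (net.pool_after[mL] && mdL.D >= 2) ? cache.pooled[mL]
                                                   : cache.act[mL];
  const int FD = net.flat_dim();
  FMat Fl(Alast.memptr(), FD, N, false, true);
  gW1 = dH1 * Fl.t();
  gb1 = arma::sum(dH1, 1);
  FMat dFl = net.W1.t() * dH1;  // (FD, N)
  const int CoutL = net.n_branch * net.filters[mL];
  FMat dA(dFl.memptr(), CoutL, (size_t)net.D_out * net.H0 * net.W0 * N, false,
          true);
  FMat dcur = dA;  // gradient wrt current module's (possibly pooled) output
  for (int m = net.n_mod - 1; m >= 0; --m) {
    const ModuleDims& md = net.dims[m];
    const int V = md.D * md.H * md.W;
    const int C = net.shapes[m * net.n_branch].C;
    const int Cout = net.n_branch * net.filters[m];
    FMat dY;
    if (net.pool_after[m] && md.D >= 2)
      pool_backward(dcur, cache.amx[m], Cout, md.D, md.H, md.W, N, dY);
    else
      dY = dcur;
    dY %= arma::conv_to<FMat>::from(cache.act[m] > 0.0f);  // ReLU
    // input of module m
    FMat Ain;
    if (m == 0) {
      Ain = X;
    } else if (net.pool_after[m - 1] && net.dims[m - 1].D >= 2) {
      Ain = cache.pooled[m - 1];
    } else {
      Ain = cache.act[m - 1];
    }
    FMat dAin;
    if (m > 0) dAin.zeros(C, (size_t)V * N);
    int off = 0;
    FMat Cols;
    for (int b = 0; b < net.n_branch; ++b) {
      const int li = m * net.n_branch + b;
      FMat dYb = dY.rows(off, off + net.filters[m] - 1);
      im2col(Ain, net.idx[li], C, V, N, Cols);
      gW[li] += dYb * Cols.t();
      gb[li] += arma::sum(dYb, 1);
      if (m > 0) {
        FMat dCols = net.Wc[li].t() * dYb;
        col2im(dCols, net.idx[li], C, V, N, dAin);
      }
      off += net.filters[m];
    }
    if (m > 0) dcur = dAin;
  }
}

// ---- R <-> C++ plumbing -------------------------------------------------

static Net net_from_r(List weights, IntegerMatrix kernels,
                      IntegerVector filters, IntegerVector pool_after,
                      IntegerVector input_dhw, int fc_width, int n_classes) {
  Net net;
  net.n_branch = kernels.nrow();
  net.n_mod = filters.size();
  net.filters = as<std::vector<int> >(filters);
  net.pool_after = as<std::vector<int> >(pool_after);
  net.D0 = input_dhw[0]; net.H0 = input_dhw[1]; net.W0 = input_dhw[2];
  net.fc_width = fc_width; net.n_classes = n_classes;
  net.shapes.resize(net.n_mod * net.n_branch);
  for (int m = 0; m < net.n_mod; ++m)
    for (int b = 0; b < net.n_branch; ++b) {
      ConvShape& s = net.shapes[m * net.n_branch + b];
      s.kd = kernels(b, 0); s.kh = kernels(b, 1); s.kw = kernels(b, 2);
      s.F = filters[m];
    }
  net.configure();
  List conv_W = weights["conv_W"], conv_b = weights["conv_b"];
  for (int i = 0; i < net.n_mod * net.n_branch; ++i) {
    net.Wc.push_back(arma::conv_to<FMat>::from(
      as<arma::mat>(conv_W[i])));
    net.bc.push_back(arma::conv_to<arma::fvec>::from(
      as<arma::vec>(conv_b[i])));
  }
  net.W1 = arma::conv_to<FMat>::from(as<arma::mat>(weights["fc1_W"]));
  net.b1 = arma::conv_to<arma::fvec>::from(as<arma::vec>(weights["fc1_b"]));
  net.W2 = arma::conv_to<FMat>::from(as<arma::mat>(weights["fc2_W"]));
  net.b2 = arma::conv_to<arma::fvec>::from(as<arma::vec>(weights["fc2_b"]));
  return net;
}

static List net_to_r(const Net& net) {
  List conv_W(net.Wc.size()), conv_b(net.bc.size());
  for (size_t i = 0; i < net.Wc.size(); ++i) {
    conv_W[i] = wrap(arma::conv_to<arma::mat>::from(net.Wc[i]));
    conv_b[i] = wrap(arma::conv_to<arma::vec>::from(net.bc[i]));
  }
  return List::create(
    _["conv_W"] = conv_W, _["conv_b"] = conv_b,
    _["fc1_W"] = wrap(arma::conv_to<arma::mat>::from(net.W1)),
    _["fc1_b"] = wrap(arma::conv_to<arma::vec>::from(net.b1)),
    _["fc2_W"] = wrap(arma::conv_to<arma::mat>::from(net.W2)),
    _["fc2_b"] = wrap(arma::conv_to<arma::vec>::from(net.b2)));
}

// [[Rcpp::export(rng = false)]]
List cnn3d_init(IntegerMatrix kernels, IntegerVector filters,
                IntegerVector pool_after, IntegerVector input_dhw,
                int fc_width, int n_classes, int seed) {
  Net net;
  net.n_branch = kernels.nrow();
  net.n_mod = filters.size();
  net.filters = as<std::vector<int> >(filters);
  net.pool_after = as<std::vector<int> >(pool_after);
  net.D0 = input_dhw[0]; net.H0 = input_dhw[1]; net.W0 = input_dhw[2];
  net.fc_width = fc_width; net.n_classes = n_classes;
  net.shapes.resize(net.n_mod * net.n_branch);
  for (int m = 0; m < net.n_mod; ++m)
    for (int b = 0; b < net.n_branch; ++b) {
      ConvShape& s = net.shapes[m * net.n_branch + b];
      s.kd = kernels(b, 0); s.kh = kernels(b, 1); s.kw = kernels(b, 2);
      s.F = filters[m];
    }
  net.configure();
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  for (int m = 0; m < net.n_mod; ++m)
    for (int b = 0; b < net.n_branch; ++b) {
      const ConvShape& s = net.shapes[m * net.n_branch + b];
      const int kvol = s.kd * s.kh * s.kw;
      const float sd = std::sqrt(2.0f / (kvol * s.C));  // He init
      FMat W(s.F, kvol * s.C);
      for (size_t i = 0; i < W.n_elem; ++i) W(i) = sd * gauss(rng);
      net.Wc.push_back(W);
      net.bc.push_back(arma::fvec(s.F, arma::fill::zeros));
    }
  const int FD = net.flat_dim();
  net.W1.set_size(fc_width, FD);
  {
    const float sd = std::sqrt(2.0f / FD);
    for (size_t i = 0; i < net.W1.n_elem; ++i) net.W1(i) = sd * gauss(rng);
  }
  net.b1 = arma::fvec(fc_width, arma::fill::zeros);
  net.W2.set_size(n_classes, fc_width);
  {
    const float sd = std::sqrt(2.0f / fc_width);
    for (size_t i = 0; i < net.W2.n_elem; ++i) net.W2(i) = sd * gauss(rng);
  }
  net.b2 = arma::fvec(n_classes, arma::fill::zeros);
  List out = net_to_r(net);
  out["flat_dim"] = FD;
  out["module_channels"] = [&] {
    IntegerVector ch(net.n_mod);
    for (int m = 0; m < net.n_mod; ++m) ch[m] = net.n_branch * net.filters[m];
    return ch;
  }();
  return out;
}

// [[Rcpp::export(rng = false)]]
List cnn3d_train(List weights, IntegerMatrix kernels, IntegerVector filters,
                 IntegerVector pool_after, IntegerVector input_dhw,
                 int fc_width, int n_classes,
                 NumericVector x, IntegerVector y,
                 NumericVector eval_x, IntegerVector eval_y,
                 int epochs, int batch_size, double lr, int seed) {
  Net net = net_from_r(weights, kernels, filters, pool_after, input_dhw,
                       fc_width, n_classes);
  const int V0 = net.D0 * net.H0 * net.W0;
  const int N = y.size();
  FMat X(1, (size_t)V0 * N);
  for (size_t i = 0; i < X.n_elem; ++i) X(i) = (float)x[i];
  arma::ivec yv(N);
  for (int n = 0; n < N; ++n) yv[n] = y[n] - 1;  // classes 1/2 -> 0/1
  const int Ne = eval_y.size();
  FMat Xe;
  arma::ivec ye;
  if (Ne > 0) {
    Xe.set_size(1, (size_t)V0 * Ne);
    for (size_t i = 0; i < Xe.n_elem; ++i) Xe(i) = (float)eval_x[i];
    ye.set_size(Ne);
    for (int n = 0; n < Ne; ++n) ye[n] = eval_y[n] - 1;
  }

  // Adam state
  std::vector<FMat*> P = net.params();
  std::vector<arma::fvec*> Pv = net.vec_params();
  std::vector<FMat> mW(P.size()), vW(P.size());
  std::vector<arma::fvec> mb(Pv.size()), vb(Pv.size());
  for (size_t i = 0; i < P.size(); ++i) {
    mW[i].zeros(P[i]->n_rows, P[i]->n_cols);
    vW[i].zeros(P[i]->n_rows, P[i]->n_cols);
  }
  for (size_t i = 0; i < Pv.size(); ++i) {
    mb[i].zeros(Pv[i]->n_elem);
    vb[i].zeros(Pv[i]->n_elem);
  }
  const float b1a = 0.9f, b2a = 0.999f, eps = 1e-8f;
  long adam_t = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(N);
  for (int n = 0; n < N; ++n) order[n] = n;

  NumericVector h_loss(epochs), h_tracc(epochs), h_teacc(epochs);
  std::vector<FMat> gW(net.Wc.size());
  std::vector<arma::fvec> gb(net.bc.size());
  FMat gW1, gW2;
  arma::fvec gb1, gb2;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int ep_correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int bn = std::min(batch_size, N - start);
      FMat Xb(1, (size_t)V0 * bn);
      arma::ivec yb(bn);
      for (int j = 0; j < bn; ++j) {
        const int src = order[start + j];
        std::memcpy(Xb.colptr((size_t)j * V0), X.colptr((size_t)src * V0),
                    (size_t)V0 * sizeof(float));
        yb[j] = yv[src];
      }
      FwdCache cache;
      FMat Pb = net_forward(net, Xb, bn, &cache);
      for (int j = 0; j < bn; ++j) {
        const float p = std::max(Pb(yb[j], j), 1e-12f);
        ep_loss -= std::log((double)p);
        arma::uword am;
        Pb.col(j).max(am);
        if ((int)am == yb[j]) ++ep_correct;
      }
      for (size_t i = 0; i < gW.size(); ++i)
        gW[i].zeros(net.Wc[i].n_rows, net.Wc[i].n_cols);
      for (size_t i = 0; i < gb.size(); ++i) gb[i].zeros(net.bc[i].n_elem);
      net_backward(net, Xb, yb, bn, cache, gW, gb, gW1, gW2, gb1, gb2);
      // Adam step
      ++adam_t;
      const float corr1 = 1.0f - std::pow(b1a, (float)adam_t);
      const float corr2 = 1.0f - std::pow(b2a, (float)adam_t);
      std::vector<FMat*> G;
      for (size_t i = 0; i < gW.size(); ++i) G.push_back(&gW[i]);
      G.push_back(&gW1); G.push_back(&gW2);
      for (size_t i = 0; i < P.size(); ++i) {
        mW[i] = b1a * mW[i] + (1.0f - b1a) * (*G[i]);
        vW[i] = b2a * vW[i] + (1.0f - b2a) * arma::square(*G[i]);
        *P[i] -= (float)lr * (mW[i] / corr1) /
                 (arma::sqrt(vW[i] / corr2) + eps);
      }
      std::vector<arma::fvec*> Gv;
      for (size_t i = 0; i < gb.size(); ++i) Gv.push_back(&gb[i]);
      Gv.push_back(&gb1); Gv.push_back(&gb2);
      for (size_t i = 0; i < Pv.size(); ++i) {
        mb[i] = b1a * mb[i] + (1.0f - b1a) * (*Gv[i]);
        vb[i] = b2a * vb[i] + (1.0f - b2a) * arma::square(*Gv[i]);
        *Pv[i] -= (float)lr * (mb[i] / corr1) /
                  (arma::sqrt(vb[i] / corr2) + eps);
      }
    }
    h_loss[ep] = ep_loss / N;
    h_tracc[ep] = (double)ep_correct / N;
    if (Ne > 0) {
      int ok = 0;
      const int chunk = 256;
      for (int start = 0; start < Ne; start += chunk) {
        const int bn = std::min(chunk, Ne - start);
        FMat Xb(Xe.colptr((size_t)start * V0), 1, (size_t)V0 * bn, false,
                true);
        FMat Pe = net_forward(net, Xb, bn, nullptr);
        for (int j = 0; j < bn; ++j) {
          arma::uword am;
          Pe.col(j).max(am);
          if ((int)am == ye[start + j]) ++ok;
        }
      }
      h_teacc[ep] = (double)ok / Ne;
    } else {
      h_teacc[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["weights"] = net_to_r(net),
    _["history"] = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["train_loss"] = h_loss,
      _["train_accuracy"] = h_tracc, _["test_accuracy"] = h_teacc));
}

// mean cross-entropy loss and exact gradients, for finite-difference checks
// [[Rcpp::export(rng = false)]]
List cnn3d_loss_grad(List weights, IntegerMatrix kernels,
                     IntegerVector filters, IntegerVector pool_after,
                     IntegerVector input_dhw, int fc_width, int n_classes,
                     NumericVector x, IntegerVector y) {
  Net net = net_from_r(weights, kernels, filters, pool_after, input_dhw,
                       fc_width, n_classes);
  const int V0 = net.D0 * net.H0 * net.W0;
  const int N = y.size();
  FMat X(1, (size_t)V0 * N);
  for (size_t i = 0; i < X.n_elem; ++i) X(i) = (float)x[i];
  arma::ivec yv(N);
  for (int n = 0; n < N; ++n) yv[n] = y[n] - 1;
  FwdCache cache;
  FMat P = net_forward(net, X, N, &cache);
  double loss = 0.0;
  for (int n = 0; n < N; ++n)
    loss -= std::log((double)std::max(P(yv[n], n), 1e-12f));
  loss /= N;
  std::vector<FMat> gW(net.Wc.size());
  std::vector<arma::fvec> gb(net.bc.size());
  for (size_t i = 0; i < gW.size(); ++i)
    gW[i].zeros(net.Wc[i].n_rows, net.Wc[i].n_cols);
  for (size_t i = 0; i < gb.size(); ++i) gb[i].zeros(net.bc[i].n_elem);
  FMat gW1, gW2;
  arma::fvec gb1, gb2;
  net_backward(net, X, yv, N, cache, gW, gb, gW1, gW2, gb1, gb2);
  List conv_gW(gW.size()), conv_gb(gb.size());
  for (size_t i = 0; i < gW.size(); ++i) {
    conv_gW[i] = wrap(arma::conv_to<arma::mat>::from(gW[i]));
    conv_gb[i] = wrap(arma::conv_to<arma::vec>::from(gb[i]));
  }
  return List::create(
    _["loss"] = loss,
    _["grad"] = List::create(
      _["conv_W"] = conv_gW, _["conv_b"] = conv_gb,
      _["fc1_W"] = wrap(arma::conv_to<arma::mat>::from(gW1)),
      _["fc1_b"] = wrap(arma::conv_to<arma::vec>::from(gb1)),
      _["fc2_W"] = wrap(arma::conv_to<arma::mat>::from(gW2)),
      _["fc2_b"] = wrap(arma::conv_to<arma::vec>::from(gb2))));
}

// [[Rcpp::export(rng = false)]]
NumericMatrix cnn3d_predict(List weights, IntegerMatrix kernels,
                            IntegerVector filters, IntegerVector pool_after,
                            IntegerVector input_dhw, int fc_width,
                            int n_classes, NumericVector x, int n) {
  Net net = net_from_r(weights, kernels, filters, pool_after, input_dhw,
                       fc_width, n_classes);
  const int V0 = net.D0 * net.H0 * net.W0;
  NumericMatrix out(n, n_classes);
  const int chunk = 256;
  FMat X(1, (size_t)V0 * n);
  for (size_t i = 0; i < X.n_elem; ++i) X(i) = (float)x[i];
  for (int start = 0; start < n; start += chunk) {
    const int bn = std::min(chunk, n - start);
    FMat Xb(X.colptr((size_t)start * V0), 1, (size_t)V0 * bn, false, true);
    FMat P = net_forward(net, Xb, bn, nullptr);
    for (int j = 0; j < bn; ++j)
      for (int c = 0; c < n_classes; ++c)
        out(start + j, c) = (double)P(c, j);
  }
  return out;
}
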