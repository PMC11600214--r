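// Residual convolutional network over L x L x 2 distance-feature
// tensors: an input 3x3 convolution to `channels` feature maps, 8
// residual blocks (conv-ReLU-conv plus identity skip, ReLU), and one
// or three per-position heads (1x1 convolution stack 64 -> 64 -> 1)
// whose output is symmetrized with its transpose.  Feature maps are
// stored (HW x C) so im2col reduces to contiguous row-run copies and
// every convolution is a single sgemm; training is plain SGD on the
// 5:1-weighted squared error over unique / non-unique residue pairs.
// The second convolution of each residual block is zero-initialized
// (blocks start as the identity), which keeps the untrained forward
// pass and early SGD numerically stable.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat FM;
typedef arma::fvec FV;

struct NetCfg {
  int in_ch, C, K, nb, nh, hh;
};

static NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.in_ch = as<int>(cfg["in_channels"]);
  c.C = as<int>(cfg["channels"]);
  c.K = as<int>(cfg["kernel"]);
  c.nb = as<int>(cfg["n_res_blocks"]);
  c.nh = as<int>(cfg["n_heads"]);
  c.hh = as<int>(cfg["head_cells"]);
  if (c.K % 2 == 0) stop("kernel size must be odd");
  return c;
}

static long net_nparams(const NetCfg& c) {
  long kk = long(c.K) * c.K;
  long n = long(c.C) * c.in_ch * kk + c.C;            // conv0
  n += long(c.nb) * 2 * (long(c.C) * c.C * kk + c.C); // blocks
  n += long(c.nh) * (long(c.hh) * c.C + c.hh + c.hh + 1); // heads
  return n;
}

// [[Rcpp::export]]
double cpp_net_nparams(List cfg) { return double(net_nparams(parse_cfg(cfg))); }

// Weight views into the flat parameter vector.  Conv weights are
// (C_out x C_in*K*K); head weights (hh x C) and (1 x hh).
struct NetViews {
  FM w0; FV b0;
  std::vector<FM> w1, w2;
  std::vector<FV> b1, b2;
  std::vector<FM> h1, h2;
  std::vector<FV> hb1, hb2;
};

static NetViews make_views(float* p, const NetCfg& c) {
  NetViews v;
  long kk = long(c.K) * c.K, off = 0;
  v.w0 = FM(p + off, c.C, c.in_ch * kk, false, true); off += c.C * c.in_ch * kk;
  v.b0 = FV(p + off, c.C, false, true); off += c.C;
  for (int b = 0; b < c.nb; ++b) {
    v.w1.emplace_back(p + off, c.C, c.C * kk, false, true); off += c.C * c.C * kk;
    v.b1.emplace_back(p + off, c.C, false, true); off += c.C;
    v.w2.emplace_back(p + off, c.C, c.C * kk, false, true); off += c.C * c.C * kk;
    v.b2.emplace_back(p + off, c.C, false, true); off += c.C;
  }
  for (int h = 0; h < c.nh; ++h) {
    v.h1.emplace_back(p + off, c.hh, c.C, false, true); off += long(c.hh) * c.C;
    v.hb1.emplace_back(p + off, c.hh, false, true); off += c.hh;
    v.h2.emplace_back(p + off, 1, c.hh, false, true); off += c.hh;
    v.hb2.emplace_back(p + off, 1, false, true); off += 1;
  }
  return v;
}

// im2col for K x K same-padding convolution on an (HW x C_in) map;
// pixel p = x + y*L.  Column c*K*K + ody*K + odx of M holds the input
// channel c shifted by (odx - pad, ody - pad).
static void im2col(const FM& A, int L, int K, FM& M) {
  const int cin = A.n_cols, pad = (K - 1) / 2, HW = L * L;
  M.zeros(HW, cin * K * K);
  for (int c = 0; c < cin; ++c) {
    const float* ac = A.colptr(c);
    for (int ody = 0; ody < K; ++ody) {
      int dy = ody - pad;
      for (int odx = 0; odx < K; ++odx) {
        int dx = odx - pad;
        float* mc = M.colptr(c * K * K + ody * K + odx);
        int x0 = std::max(0, -dx), x1 = std::min(L, L - dx);
        if (x1 <= x0) continue;
        int y0 = std::max(0, -dy), y1 = std::min(L, L - dy);
        for (int y = y0; y < y1; ++y)
          std::memcpy(mc + x0 + y * L, ac + (x0 + dx) + (y + dy) * L,
                      (x1 - x0) * sizeof(float));
      }
    }
  }
}

static void col2im(const FM& dM, int L, int K, FM& dA) {
  const int cin = dA.n_cols, pad = (K - 1) / 2;
  for (int c = 0; c < cin; ++c) {
    float* ac = dA.colptr(c);
    for (int ody = 0; ody < K; ++ody) {
      int dy = ody - pad;
      for (int odx = 0; odx < K; ++odx) {
        int dx = odx - pad;
        const float* mc = dM.colptr(c * K * K + ody * K + odx);
        int x0 = std::max(0, -dx), x1 = std::min(L, L - dx);
        if (x1 <= x0) continue;
        int y0 = std::max(0, -dy), y1 = std::min(L, L - dy);
        for (int y = y0; y < y1; ++y) {
          float* dst = ac + (x0 + dx) + (y + dy) * L;
          const float* src = mc + x0 + y * L;
          for (int x = 0; x < x1 - x0; ++x) dst[x] += src[x];
        }
      }
    }
  }
}

static inline void relu_inplace(FM& A) {
  float* p = A.memptr();
  for (arma::uword i = 0; i < A.n_elem; ++i)
    if (p[i] < 0.0f) p[i] = 0.0f;
}

// zero entries of dA where the activation act is 0 (ReLU backward)
static inline void relu_mask(FM& dA, const FM& act) {
  float* d = dA.memptr();
  const float* a = act.memptr();
  for (arma::uword i = 0; i < dA.n_elem; ++i)
    if (a[i] <= 0.0f) d[i] = 0.0f;
}

// Y (HW x Cout) = im2col(A) * W', using the caller's scratch M
static FM conv_fwd(const FM& A, const FM& W, const FV& b, int L, int K,
                   FM& M) {
  im2col(A, L, K, M);
  FM Y = M * W.t();
  Y.each_row() += b.t();
  return Y;
}

// backward: accumulate dW, db; return dA
static FM conv_bwd(const FM& A, const FM& W, const FM& dY, int L, int K,
                   FM& dW, FV& db, FM& M) {
  im2col(A, L, K, M);
  dW += dY.t() * M;
  db += arma::sum(dY, 0).t();
  FM dM = dY * W;
  FM dA(A.n_rows, A.n_cols, arma::fill::zeros);
  col2im(dM, L, K, dA);
  return dA;
}

struct FwdCache {
  FM a0;                    // input (HW x in_ch)
  FM act_in;                // relu(conv0)
  std::vector<FM> mid, out; // per block
  std::vector<FM> hu;       // per head hidden
  std::vector<FV> raw;      // per head raw output (HW)
  FM scratch;               // im2col buffer
};

static void net_forward(const NetViews& v, const NetCfg& c, const FM& x,
                        int L, FwdCache& f) {
  f.a0 = x;
  f.act_in = conv_fwd(x, v.w0, v.b0, L, c.K, f.scratch);
  relu_inplace(f.act_in);
  f.mid.clear(); f.out.clear(); f.hu.clear(); f.raw.clear();
  const FM* A = &f.act_in;
  for (int b = 0; b < c.nb; ++b) {
    FM Z = conv_fwd(*A, v.w1[b], v.b1[b], L, c.K, f.scratch);
    relu_inplace(Z);
    f.mid.push_back(std::move(Z));
    FM Z2 = conv_fwd(f.mid[b], v.w2[b], v.b2[b], L, c.K, f.scratch);
    Z2 += *A;
    relu_inplace(Z2);
    f.out.push_back(std::move(Z2));
    A = &f.out[b];
  }
  for (int h = 0; h < c.nh; ++h) {
    FM U = (*A) * v.h1[h].t();
    U.each_row() += v.hb1[h].t();
    relu_inplace(U);
    f.hu.push_back(std::move(U));
    FV R = f.hu[h] * v.h2[h].t();
    R += v.hb2[h](0);
    f.raw.push_back(std::move(R));
  }
}

// symmetrized head output as an L x L matrix (pixel p = x + y*L is
// column-major, so the vector reshapes directly)
static FM head_sym(const FV& raw, int L) {
  FM M(const_cast<float*>(raw.memptr()), L, L);
  return 0.5f * (M + M.t());
}

// weighted mean squared error over included pairs
static double net_loss(const FwdCache& f, const NetCfg& c, int L,
                       const std::vector<FM>& targets, const FM& wt,
                       double npair, std::vector<FM>* dsym) {
  double loss = 0.0;
  for (int h = 0; h < c.nh; ++h) {
    FM S = head_sym(f.raw[h], L);
    FM E = S - targets[h];
    loss += arma::accu(wt % E % E) / (npair * c.nh);
    if (dsym)
      (*dsym)[h] = (2.0f / float(npair * c.nh)) * (wt % E);
  }
  return loss;
}

static void net_backward(const NetViews& v, const NetCfg& c, int L,
                         const FwdCache& f, const std::vector<FM>& dsym,
                         NetViews& g, FM& scratch) {
  const FM& top = c.nb > 0 ? f.out[c.nb - 1] : f.act_in;
  FM dA(L * L, c.C, arma::fill::zeros);
  for (int h = 0; h < c.nh; ++h) {
    // through symmetrization into the raw head vector
    FM G = 0.5f * (dsym[h] + dsym[h].t());
    FV dRaw(G.memptr(), L * L);
    g.h2[h] += dRaw.t() * f.hu[h];
    g.hb2[h](0) += arma::accu(dRaw);
    FM dU = dRaw * v.h2[h];
    relu_mask(dU, f.hu[h]);
    g.h1[h] += dU.t() * top;
    g.hb1[h] += arma::sum(dU, 0).t();
    dA += dU * v.h1[h];
  }
  for (int b = c.nb - 1; b >= 0; --b) {
    const FM& Ain = b > 0 ? f.out[b - 1] : f.act_in;
    relu_mask(dA, f.out[b]);
    FM dMid = conv_bwd(f.mid[b], v.w2[b], dA, L, c.K, g.w2[b], g.b2[b],
                       scratch);
    relu_mask(dMid, f.mid[b]);
    FM dPrev = conv_bwd(Ain, v.w1[b], dMid, L, c.K, g.w1[b], g.b1[b],
                        scratch);
    dA += dPrev; // identity skip
  }
  relu_mask(dA, f.act_in);
  im2col(f.a0, L, c.K, scratch);
  g.w0 += dA.t() * scratch;
  g.b0 += arma::sum(dA, 0).t();
}

// [[Rcpp::export]]
NumericVector cpp_net_init(List cfg, int seed) {
  NetCfg c = parse_cfg(cfg);
  long np = net_nparams(c);
  FV p(np, arma::fill::zeros);
  NetViews v = make_views(p.memptr(), c);
  std::mt19937_64 rng(seed);
  std::normal_distribution<float> gauss(0.0f, 1.0f);
  auto he = [&](FM& W, int fan_in) {
    float s = std::sqrt(2.0f / float(fan_in));
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = s * gauss(rng);
  };
  int kk = c.K * c.K;
  he(v.w0, c.in_ch * kk);
  for (int b = 0; b < c.nb; ++b) {
    he(v.w1[b], c.C * kk);
    // v.w2 stays zero: each block starts as the identity
  }
  for (int h = 0; h < c.nh; ++h) {
    he(v.h1[h], c.C);
    he(v.h2[h], c.hh);
  }
  return NumericVector(p.begin(), p.end());
}

static FM input_to_fm(const NumericVector& x, const NetCfg& c, int* L) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[0] != dim[1] || dim[2] != c.in_ch)
    stop("input must be an L x L x in_channels array");
  *L = dim[0];
  int HW = *L * *L;
  FM A(HW, c.in_ch);
  for (int ch = 0; ch < c.in_ch; ++ch)
    for (int p = 0; p < HW; ++p)
      A(p, ch) = float(x[p + ch * HW]);
  return A;
}

static FV to_fv(const NumericVector& params) {
  FV p(params.size());
  for (long i = 0; i < (long)params.size(); ++i) p(i) = float(params[i]);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_net_forward(NumericVector params, List cfg,
                              NumericVector x, bool clamp = true) {
  NetCfg c = parse_cfg(cfg);
  int L;
  FM A = input_to_fm(x, c, &L);
  if (L < c.K) stop("matrix size L must be >= kernel size");
  FV p = to_fv(params);
  NetViews v = make_views(p.memptr(), c);
  FwdCache f;
  net_forward(v, c, A, L, f);
  NumericVector out(size_t(L) * L * c.nh);
  for (int h = 0; h < c.nh; ++h) {
    FM S = head_sym(f.raw[h], L);
    if (clamp)
      S.transform([](float z) {
        return std::min(std::max(z, 0.0f), 1.0f - 1e-7f);
      });
    for (int pidx = 0; pidx < L * L; ++pidx)
      out[pidx + size_t(h) * L * L] = double(S(pidx));
  }
  out.attr("dim") = IntegerVector::create(L, L, c.nh);
  return out;
}

static std::vector<FM> target_list(const NumericVector& y, const NetCfg& c,
                                   int L) {
  std::vector<FM> t;
  for (int h = 0; h < c.nh; ++h) {
    FM T(L, L);
    for (int p = 0; p < L * L; ++p) T(p) = float(y[p + size_t(h) * L * L]);
    t.push_back(std::move(T));
  }
  return t;
}

static double count_pairs(const FM& wt) {
  double n = 0;
  for (arma::uword i = 0; i < wt.n_elem; ++i)
    if (wt(i) > 0.0f) n += 1;
  return n < 1 ? 1 : n;
}

// [[Rcpp::export]]
List cpp_net_loss_grad(NumericVector params, List cfg, NumericVector x,
                       NumericVector y, NumericMatrix w) {
  NetCfg c = parse_cfg(cfg);
  int L;
  FM A = input_to_fm(x, c, &L);
  FV p = to_fv(params);
  NetViews v = make_views(p.memptr(), c);
  FwdCache f;
  net_forward(v, c, A, L, f);
  std::vector<FM> targets = target_list(y, c, L);
  FM wt(L, L);
  for (int i = 0; i < L * L; ++i) wt(i) = float(w[i]);
  std::vector<FM> dsym(c.nh);
  double loss = net_loss(f, c, L, targets, wt, count_pairs(wt), &dsym);
  FV gvec(p.n_elem, arma::fill::zeros);
  NetViews g = make_views(gvec.memptr(), c);
  net_backward(v, c, L, f, dsym, g, f.scratch);
  return List::create(_["loss"] = loss,
                      _["grad"] = NumericVector(gvec.begin(), gvec.end()));
}

// Full SGD training loop.  xs/ys/ws are lists of examples; train_idx /
// val_idx are 1-based indices into them.  Returns the best-validation
// parameters (or final when no validation set), loss history, and the
// number of SGD steps executed.  Stops early once the epoch-mean
// training loss drops below stop_train_loss.
// [[Rcpp::export]]
List cpp_net_train(NumericVector params, List cfg, List xs, List ys,
                   List ws, IntegerVector train_idx, IntegerVector val_idx,
                   double lr, int n_epochs, int seed,
                   double stop_train_loss) {
  NetCfg c = parse_cfg(cfg);
  FV p = to_fv(params);
  NetViews v = make_views(p.memptr(), c);
  FV gvec(p.n_elem, arma::fill::zeros);
  NetViews g = make_views(gvec.memptr(), c);

  int ntr = train_idx.size();
  std::vector<FM> Ax(xs.size()), Wt(xs.size());
  std::vector<std::vector<FM> > Ty(xs.size());
  std::vector<int> Ls(xs.size());
  std::vector<double> Np(xs.size());
  for (int e = 0; e < xs.size(); ++e) {
    NumericVector x = xs[e];
    Ax[e] = input_to_fm(x, c, &Ls[e]);
    NumericVector y = ys[e];
    Ty[e] = target_list(y, c, Ls[e]);
    NumericMatrix w = ws[e];
    FM wt(Ls[e], Ls[e]);
    for (int i = 0; i < Ls[e] * Ls[e]; ++i) wt(i) = float(w[i]);
    Wt[e] = wt;
    Np[e] = count_pairs(wt);
  }

  std::mt19937_64 rng(seed);
  std::vector<int> order(train_idx.begin(), train_idx.end());
  std::vector<double> h_epoch, h_train, h_val;
  FV best = p;
  double best_val = std::numeric_limits<double>::infinity();
  long steps = 0;
  FwdCache f;

  for (int ep = 0; ep < n_epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tl = 0.0;
    for (int t = 0; t < ntr; ++t) {
      int e = order[t] - 1;
      net_forward(v, c, Ax[e], Ls[e], f);
      std::vector<FM> dsym(c.nh);
      tl += net_loss(f, c, Ls[e], Ty[e], Wt[e], Np[e], &dsym);
      gvec.zeros();
      net_backward(v, c, Ls[e], f, dsym, g, f.scratch);
      p -= float(lr) * gvec;
      ++steps;
    }
    tl /= ntr;
    double vl = NA_REAL;
    if (val_idx.size() > 0) {
      vl = 0.0;
      for (int t = 0; t < val_idx.size(); ++t) {
        int e = val_idx[t] - 1;
        net_forward(v, c, Ax[e], Ls[e], f);
        vl += net_loss(f, c, Ls[e], Ty[e], Wt[e], Np[e], nullptr);
      }
      vl /= val_idx.size();
      if (vl < best_val) { best_val = vl; best = p; }
    }
    h_epoch.push_back(ep + 1);
    h_train.push_back(tl);
    h_val.push_back(vl);
    Rcpp::checkUserInterrupt();
    if (tl < stop_train_loss) break;
  }
  if (val_idx.size() == 0) best = p;
  return List::create(
      _["params"] = NumericVector(best.begin(), best.end()),
      _["final_params"] = NumericVector(p.begin(), p.end()),
      _["epoch"] = wrap(h_epoch), _["train_loss"] = wrap(h_train),
      _["val_loss"] = wrap(h_val), _["steps"] = double(steps),
      _["best_val"] = best_val);
}
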