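// Whole-graph executor: runs forward, the class-weighted cross-entropy and
// backward for a batch in a single call, keeping every activation on the C++
// side in float32. The R layer only ships the (small) parameter groups in and
// the gradients out, so per-batch overhead is independent of the activation
// volume.
//
// Convolutions use the 1-D shift-GEMM formulation: a stride-1 same-padded
// convolution of kernel width k is the sum over k tap positions of a plain
// GEMM between a shifted view of the input and the tap's (Cin x Cout) weight
// slice. No im2col buffer is ever materialized, and every tap runs at BLAS
// speed.
//
// Node spec (one R list per node, topologically ordered):
//   op      : 0 input, 1 conv, 2 dwconv, 3 bn, 4 relu, 5 maxpool3,
//             6 avgpool, 7 gap, 8 add, 9 concat
//   inputs  : 0-based indices of upstream nodes
//   k       : kernel size (conv/dwconv/avgpool)
//   w, b    : conv weights (Cout x Cin*k, w(o, c*k+j)) and optional bias
//   gamma, beta, rmean, rvar, eps, momentum : batch-norm pieces
//   need_gx : gradient must flow into this node's inputs
//   need_pg : parameter gradients required (trainable group)
//
// A linear layer is a k = 1 conv on the (1, C, N) cube left by gap.

#include <RcppArmadillo.h>
#include <chrono>
#ifdef __GLIBC__
#include <malloc.h>
// Large activation buffers (tens of MB) are allocated and freed on every
// batch; keep them on the heap instead of per-call mmap/munmap so the pages
// stay warm across calls.
static const bool malloc_tuned = [] {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return true;
}();
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

enum OpCode { OP_INPUT = 0, OP_CONV = 1, OP_DWCONV = 2, OP_BN = 3, OP_RELU = 4,
              OP_MAXPOOL3 = 5, OP_AVGPOOL = 6, OP_GAP = 7, OP_ADD = 8,
              OP_CONCAT = 9 };

struct GNode {
  int op = OP_INPUT;
  std::vector<int> inputs;
  int k = 1;
  bool has_bias = false, need_gx = false, need_pg = false;
  std::vector<fmat> wtaps;   // per-tap (Cin x Cout) weight slices
  int cin = 0, cout = 0;
  fvec b;
  fvec gamma, beta, rmean, rvar;
  double eps = 1e-5, momentum = 0.1;
  // caches
  fvec bn_mean, bn_invstd;
  Cube<short> mp_idx;
};

// forward taps: Y[t] += X[t + j - pad] * W_j
static void conv_fw(const GNode& nd, const fcube& x, fcube& y) {
  const int L = x.n_rows, N = x.n_slices;
  const int k = nd.k, pad = (k - 1) / 2;
  y.zeros(L, nd.cout, N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < k; ++j) {
      const int s = j - pad;
      const int lo = std::max(0, -s), hi = std::min(L, L - s);
      if (hi <= lo) continue;
      y.slice(n).rows(lo, hi - 1) += x.slice(n).rows(lo + s, hi - 1 + s) * nd.wtaps[j];
    }
    if (nd.has_bias) y.slice(n).each_row() += nd.b.t();
  }
}

static void conv_bw(const GNode& nd, const fcube& x, const fcube& gy,
                    std::vector<fmat>& gwtaps, fvec& gb, fcube* gx) {
  const int L = x.n_rows, N = x.n_slices;
  const int k = nd.k, pad = (k - 1) / 2;
  if (nd.need_pg) {
    gwtaps.assign(k, fmat(nd.cin, nd.cout, fill::zeros));
    if (nd.has_bias) gb.zeros(nd.cout);
  }
  if (gx) gx->zeros(L, nd.cin, N);
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < k; ++j) {
      const int s = j - pad;
      const int lo = std::max(0, -s), hi = std::min(L, L - s);
      if (hi <= lo) continue;
      if (nd.need_pg)
        gwtaps[j] += x.slice(n).rows(lo + s, hi - 1 + s).t() * gy.slice(n).rows(lo, hi - 1);
      if (gx)
        gx->slice(n).rows(lo + s, hi - 1 + s) += gy.slice(n).rows(lo, hi - 1) * nd.wtaps[j].t();
    }
    if (nd.need_pg && nd.has_bias) gb += sum(gy.slice(n), 0).t();
  }
}

// depthwise: per tap, an elementwise row-broadcast multiply-accumulate
static void dwconv_fw(const GNode& nd, const fcube& x, fcube& y) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int k = nd.k, pad = (k - 1) / 2;
  y.zeros(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < k; ++j) {
      const int s = j - pad;
      const int lo = std::max(0, -s), hi = std::min(L, L - s);
      if (hi <= lo) continue;
      // wtaps[j] is (C x 1): tap j of every channel
      const fmat& src = x.slice(n);
      fmat& dst = y.slice(n);
      for (int c = 0; c < C; ++c) {
        const float wj = nd.wtaps[j](c, 0);
        const float* __restrict xc = src.colptr(c) + lo + s;
        float* __restrict yc = dst.colptr(c) + lo;
        const int len = hi - lo;
        for (int t = 0; t < len; ++t) yc[t] += wj * xc[t];
      }
    }
}

static void dwconv_bw(const GNode& nd, const fcube& x, const fcube& gy,
                      std::vector<fmat>& gwtaps, fcube* gx) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int k = nd.k, pad = (k - 1) / 2;
  if (nd.need_pg) gwtaps.assign(k, fmat(C, 1, fill::zeros));
  if (gx) gx->zeros(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int j = 0; j < k; ++j) {
      const int s = j - pad;
      const int lo = std::max(0, -s), hi = std::min(L, L - s);
      if (hi <= lo) continue;
      const int len = hi - lo;
      for (int c = 0; c < C; ++c) {
        const float* __restrict xc = x.slice(n).colptr(c) + lo + s;
        const float* __restrict gc = gy.slice(n).colptr(c) + lo;
        if (nd.need_pg) {
          float acc = 0.0f;
          for (int t = 0; t < len; ++t) acc += gc[t] * xc[t];
          gwtaps[j](c, 0) += acc;
        }
        if (gx) {
          const float wj = nd.wtaps[j](c, 0);
          float* __restrict oc = gx->slice(n).colptr(c) + lo + s;
          for (int t = 0; t < len; ++t) oc[t] += wj * gc[t];
        }
      }
    }
}

static void bn_fw(GNode& nd, const fcube& x, fcube& y, bool training) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const double M = (double)L * N;
  fvec mu(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const float* xc = x.slice(n).colptr(c);
        for (int i = 0; i < L; ++i) { s += xc[i]; s2 += (double)xc[i] * xc[i]; }
      }
      mu(c) = (float)(s / M);
      var(c) = (float)std::max(0.0, s2 / M - (s / M) * (s / M));
    }
    const float unbias = M > 1 ? (float)(M / (M - 1.0)) : 1.0f;
    nd.rmean = (1 - (float)nd.momentum) * nd.rmean + (float)nd.momentum * mu;
    nd.rvar = (1 - (float)nd.momentum) * nd.rvar + (float)nd.momentum * var * unbias;
  } else { mu = nd.rmean; var = nd.rvar; }
  nd.bn_mean = mu;
  nd.bn_invstd = 1.0f / sqrt(var + (float)nd.eps);
  y.set_size(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float a = nd.gamma(c) * nd.bn_invstd(c);
      const float b0 = nd.beta(c) - a * mu(c);
      const float* xc = x.slice(n).colptr(c);
      float* yc = y.slice(n).colptr(c);
      for (int i = 0; i < L; ++i) yc[i] = a * xc[i] + b0;
    }
}

static void bn_bw(const GNode& nd, const fcube& x, const fcube& gy,
                  fvec& ggamma, fvec& gbeta, fcube* gx, bool training) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const double M = (double)L * N;
  ggamma.zeros(C); gbeta.zeros(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    const float mu = nd.bn_mean(c), is = nd.bn_invstd(c);
    for (int n = 0; n < N; ++n) {
      const float* xc = x.slice(n).colptr(c);
      const float* gc = gy.slice(n).colptr(c);
      for (int i = 0; i < L; ++i) {
        sg += gc[i];
        sgx += (double)gc[i] * (xc[i] - mu) * is;
      }
    }
    gbeta(c) = (float)sg; ggamma(c) = (float)sgx;
  }
  if (gx) {
    gx->set_size(L, C, N);
    for (int c = 0; c < C; ++c) {
      const float mu = nd.bn_mean(c), is = nd.bn_invstd(c);
      const float a = nd.gamma(c) * is;
      const float mg = training ? (float)(gbeta(c) / M) : 0.0f;
      const float mgx = training ? (float)(ggamma(c) / M) : 0.0f;
      for (int n = 0; n < N; ++n) {
        const float* xc = x.slice(n).colptr(c);
        const float* gc = gy.slice(n).colptr(c);
        float* oc = gx->slice(n).colptr(c);
        for (int i = 0; i < L; ++i) {
          const float xhat = (xc[i] - mu) * is;
          oc[i] = a * (gc[i] - mg - xhat * mgx);
        }
      }
    }
  }
}

// split flat (Cout x Cin*k) weights into per-tap (Cin x Cout) slices
static void load_taps(GNode& nd, const mat& wflat, bool depthwise) {
  const int k = nd.k;
  nd.wtaps.assign(k, fmat());
  if (depthwise) {
    // wflat is (k x C)
    const int C = wflat.n_cols;
    nd.cin = nd.cout = C;
    for (int j = 0; j < k; ++j) {
      nd.wtaps[j].set_size(C, 1);
      for (int c = 0; c < C; ++c) nd.wtaps[j](c, 0) = (float)wflat(j, c);
    }
  } else {
    const int Cout = wflat.n_rows, Cin = wflat.n_cols / k;
    nd.cin = Cin; nd.cout = Cout;
    for (int j = 0; j < k; ++j) {
      nd.wtaps[j].set_size(Cin, Cout);
      for (int o = 0; o < Cout; ++o)
        for (int c = 0; c < Cin; ++c)
          nd.wtaps[j](c, o) = (float)wflat(o, c * k + j);
    }
  }
}

// reassemble gradient taps into the flat R-side layout
static mat taps_to_flat(const std::vector<fmat>& taps, bool depthwise) {
  const int k = taps.size();
  if (depthwise) {
    const int C = taps[0].n_rows;
    mat g(k, C);
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < C; ++c) g(j, c) = taps[j](c, 0);
    return g;
  }
  const int Cin = taps[0].n_rows, Cout = taps[0].n_cols;
  mat g(Cout, Cin * k);
  for (int j = 0; j < k; ++j)
    for (int o = 0; o < Cout; ++o)
      for (int c = 0; c < Cin; ++c) g(o, c * k + j) = taps[j](c, o);
  return g;
}

static double prof_fw[12], prof_bw[12];

// [[Rcpp::export]]
NumericMatrix cpp_graph_prof() {
  NumericMatrix m(2, 12);
  for (int i = 0; i < 12; ++i) { m(0, i) = prof_fw[i]; m(1, i) = prof_bw[i]; }
  std::fill(prof_fw, prof_fw + 12, 0.0);
  std::fill(prof_bw, prof_bw + 12, 0.0);
  return m;
}

static inline double now_s() {
  return std::chrono::duration<double>(
    std::chrono::steady_clock::now().time_since_epoch()).count();
}

// [[Rcpp::export]]
List cpp_graph_run(List nodespec, const arma::cube& x, bool training,
                   Rcpp::Nullable<Rcpp::IntegerVector> y_,
                   Rcpp::Nullable<Rcpp::NumericVector> w_,
                   bool do_backward) {
  const int nn = nodespec.size();
  std::vector<GNode> nodes(nn);
  for (int i = 0; i < nn; ++i) {
    List ns = nodespec[i];
    GNode& nd = nodes[i];
    nd.op = as<int>(ns["op"]);
    IntegerVector iv = ns["inputs"];
    nd.inputs.assign(iv.begin(), iv.end());
    if (ns.containsElementNamed("k")) nd.k = as<int>(ns["k"]);
    nd.need_gx = as<bool>(ns["need_gx"]);
    nd.need_pg = as<bool>(ns["need_pg"]);
    if (nd.op == OP_CONV || nd.op == OP_DWCONV) {
      load_taps(nd, as<mat>(ns["w"]), nd.op == OP_DWCONV);
      if (nd.op == OP_CONV && ns.containsElementNamed("b") && !Rf_isNull(ns["b"])) {
        nd.b = conv_to<fvec>::from(as<vec>(ns["b"]));
        nd.has_bias = true;
      }
    } else if (nd.op == OP_BN) {
      nd.gamma = conv_to<fvec>::from(as<vec>(ns["gamma"]));
      nd.beta = conv_to<fvec>::from(as<vec>(ns["beta"]));
      nd.rmean = conv_to<fvec>::from(as<vec>(ns["rmean"]));
      nd.rvar = conv_to<fvec>::from(as<vec>(ns["rvar"]));
      nd.eps = as<double>(ns["eps"]); nd.momentum = as<double>(ns["momentum"]);
    }
  }

  // ---- forward ----
  std::vector<fcube> act(nn);
  act[0] = conv_to<fcube>::from(x);
  for (int i = 1; i < nn; ++i) {
    GNode& nd = nodes[i];
    const fcube& a = act[nd.inputs[0]];
    const double t_op = now_s();
    switch (nd.op) {
      case OP_CONV: conv_fw(nd, a, act[i]); break;
      case OP_DWCONV: dwconv_fw(nd, a, act[i]); break;
      case OP_BN: bn_fw(nd, a, act[i], training); break;
      case OP_RELU: {
        act[i] = a;
        act[i].for_each([](float& v) { if (v < 0) v = 0; });
        break;
      }
      case OP_MAXPOOL3: {
        const int L = a.n_rows, C = a.n_cols, N = a.n_slices;
        act[i].set_size(L, C, N);
        nd.mp_idx.set_size(L, C, N);
        for (int n = 0; n < N; ++n)
          for (int c = 0; c < C; ++c) {
            const float* xc = a.slice(n).colptr(c);
            float* yc = act[i].slice(n).colptr(c);
            short* ic = nd.mp_idx.slice(n).colptr(c);
            for (int t = 0; t < L; ++t) {
              float best = xc[t]; short off = 0;
              if (t > 0 && xc[t - 1] > best) { best = xc[t - 1]; off = -1; }
              if (t < L - 1 && xc[t + 1] > best) { best = xc[t + 1]; off = 1; }
              yc[t] = best; ic[t] = off;
            }
          }
        break;
      }
      case OP_AVGPOOL: {
        const int L = a.n_rows, C = a.n_cols, N = a.n_slices, k = nd.k, Lo = L / k;
        act[i].set_size(Lo, C, N);
        for (int n = 0; n < N; ++n)
          for (int c = 0; c < C; ++c) {
            const float* xc = a.slice(n).colptr(c);
            float* yc = act[i].slice(n).colptr(c);
            for (int o = 0; o < Lo; ++o) {
              float s = 0.0f;
              for (int j = 0; j < k; ++j) s += xc[o * k + j];
              yc[o] = s / k;
            }
          }
        break;
      }
      case OP_GAP: {
        const int C = a.n_cols, N = a.n_slices;
        act[i].set_size(1, C, N);
        for (int n = 0; n < N; ++n)
          act[i].slice(n).row(0) = mean(a.slice(n), 0);
        break;
      }
      case OP_ADD: act[i] = a + act[nd.inputs[1]]; break;
      case OP_CONCAT: {
        int C = 0;
        for (int in : nd.inputs) C += act[in].n_cols;
        const int L = a.n_rows, N = a.n_slices;
        act[i].set_size(L, C, N);
        int at = 0;
        for (int in : nd.inputs) {
          const fcube& s = act[in];
          act[i].cols(at, at + s.n_cols - 1) = s;
          at += s.n_cols;
        }
        break;
      }
      default: stop("unknown op code");
    }
    prof_fw[nd.op] += now_s() - t_op;
  }

  // logits from the final (1, K, N) cube -> (N x K), back in double
  const fcube& out = act[nn - 1];
  const int K = out.n_cols, N = out.n_slices;
  mat logits(N, K);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < K; ++c) logits(n, c) = out(0, c, n);

  // batch-norm running-stat updates back to R
  List bn_updates(nn);
  if (training)
    for (int i = 0; i < nn; ++i)
      if (nodes[i].op == OP_BN)
        bn_updates[i] = List::create(
          _["rmean"] = conv_to<vec>::from(nodes[i].rmean),
          _["rvar"] = conv_to<vec>::from(nodes[i].rvar));

  double loss = NA_REAL;
  List grads(nn);
  if (do_backward) {
    if (y_.isNull() || w_.isNull()) stop("backward needs labels and weights");
    IntegerVector y(y_); NumericVector w(w_);
    // class-weighted softmax cross-entropy
    mat p = logits;
    for (int n = 0; n < N; ++n) {
      rowvec r = p.row(n) - p.row(n).max();
      r = exp(r); r /= accu(r);
      p.row(n) = r;
    }
    double wsum = 0.0; loss = 0.0;
    mat glog(N, K, fill::zeros);
    for (int n = 0; n < N; ++n) {
      const int cls = y[n] - 1;
      const double wy = w[cls];
      wsum += wy;
      loss += -wy * std::log(p(n, cls) + 1e-12);
      glog.row(n) = p.row(n) * wy;
      glog(n, cls) -= wy;
    }
    loss /= wsum;
    glog /= wsum;

    std::vector<fcube> ga(nn);
    std::vector<bool> have(nn, false);
    ga[nn - 1].set_size(1, K, N);
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < K; ++c) ga[nn - 1](0, c, n) = (float)glog(n, c);
    have[nn - 1] = true;

    auto acc = [&](int idx, fcube g) { // by value: callers may move in
      if (have[idx]) ga[idx] += g;
      else { ga[idx] = std::move(g); have[idx] = true; }
    };

    for (int i = nn - 1; i >= 1; --i) {
      GNode& nd = nodes[i];
      if (!have[i]) continue;
      if (!nd.need_pg && !nd.need_gx) { ga[i].reset(); continue; }
      const fcube& a = act[nd.inputs[0]];
      const fcube& gy = ga[i];
      fcube gxl;
      fcube* gxp = nd.need_gx ? &gxl : nullptr;
      const double t_op = now_s();
      switch (nd.op) {
        case OP_CONV: {
          std::vector<fmat> gwt; fvec gb;
          conv_bw(nd, a, gy, gwt, gb, gxp);
          if (nd.need_pg) {
            if (nd.has_bias)
              grads[i] = List::create(_["w"] = taps_to_flat(gwt, false),
                                      _["b"] = conv_to<vec>::from(gb));
            else grads[i] = List::create(_["w"] = taps_to_flat(gwt, false));
          }
          break;
        }
        case OP_DWCONV: {
          std::vector<fmat> gwt;
          dwconv_bw(nd, a, gy, gwt, gxp);
          if (nd.need_pg)
            grads[i] = List::create(_["w"] = taps_to_flat(gwt, true));
          break;
        }
        case OP_BN: {
          fvec gg, gb;
          bn_bw(nd, a, gy, gg, gb, gxp, training);
          if (nd.need_pg)
            grads[i] = List::create(_["gamma"] = conv_to<vec>::from(gg),
                                    _["beta"] = conv_to<vec>::from(gb));
          break;
        }
        case OP_RELU: {
          if (gxp) {
            gxl = gy;
            const float* ap = a.memptr(); float* gp = gxl.memptr();
            for (uword t = 0; t < a.n_elem; ++t) if (ap[t] <= 0) gp[t] = 0;
          }
          break;
        }
        case OP_MAXPOOL3: {
          if (gxp) {
            gxl.zeros(a.n_rows, a.n_cols, a.n_slices);
            const int L = a.n_rows, C = a.n_cols, Nn = a.n_slices;
            for (int n = 0; n < Nn; ++n)
              for (int c = 0; c < C; ++c) {
                const float* gc = gy.slice(n).colptr(c);
                const short* ic = nd.mp_idx.slice(n).colptr(c);
                float* xc = gxl.slice(n).colptr(c);
                for (int t = 0; t < L; ++t) xc[t + ic[t]] += gc[t];
              }
          }
          break;
        }
        case OP_AVGPOOL: {
          if (gxp) {
            const int k = nd.k, Lo = gy.n_rows, C = gy.n_cols, Nn = gy.n_slices;
            gxl.zeros(a.n_rows, C, Nn);
            for (int n = 0; n < Nn; ++n)
              for (int c = 0; c < C; ++c) {
                const float* gc = gy.slice(n).colptr(c);
                float* xc = gxl.slice(n).colptr(c);
                for (int o = 0; o < Lo; ++o) {
                  const float gv = gc[o] / k;
                  for (int j = 0; j < k; ++j) xc[o * k + j] += gv;
                }
              }
          }
          break;
        }
        case OP_GAP: {
          if (gxp) {
            const int L = a.n_rows, C = a.n_cols, Nn = a.n_slices;
            gxl.set_size(L, C, Nn);
            for (int n = 0; n < Nn; ++n)
              for (int c = 0; c < C; ++c)
                gxl.slice(n).col(c).fill(gy(0, c, n) / L);
          }
          break;
        }
        case OP_ADD: {
          if (nodes[nd.inputs[0]].op != OP_INPUT) acc(nd.inputs[0], gy);
          if (nodes[nd.inputs[1]].op != OP_INPUT) acc(nd.inputs[1], gy);
          ga[i].reset();
          continue; // both inputs handled
        }
        case OP_CONCAT: {
          int at = 0;
          for (int in : nd.inputs) {
            const int C = act[in].n_cols;
            acc(in, gy.cols(at, at + C - 1));
            at += C;
          }
          ga[i].reset();
          continue;
        }
      }
      prof_bw[nd.op] += now_s() - t_op;
      if (nd.need_gx && nd.inputs[0] != 0) acc(nd.inputs[0], std::move(gxl));
      ga[i].reset();
    }
  }

  return List::create(_["logits"] = logits, _["loss"] = loss,
                      _["grads"] = grads, _["bn_updates"] = bn_updates);
}
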