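// Low-level 1-D neural-network operators on batched time series.
// Layout convention: a batch is an arma::cube (n_samples_per_lead L, channels C,
// batch N) so that 1x1 convolutions reduce to one GEMM per slice and the time
// axis is contiguous. All convolutions are stride 1 with symmetric "same"
// padding (odd kernels only), which covers every architecture in the package.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline void im2col(const mat& xs, mat& X, int k, int pad) {
  const int L = xs.n_rows, Cin = xs.n_cols;
  X.zeros();
  for (int c = 0; c < Cin; ++c) {
    for (int j = 0; j < k; ++j) {
      const int s = j - pad;
      const int lo = std::max(0, -s), hi = std::min(L, L - s);
      if (hi > lo)
        X.submat(lo, c * k + j, hi - 1, c * k + j) = xs.col(c).subvec(lo + s, hi - 1 + s);
    }
  }
}

// weights w: (Cout x Cin*k), w(o, c*k + j); bias b length Cout (or length 0)
// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& x, const arma::mat& w, const arma::vec& b, int k) {
  const int L = x.n_rows, Cin = x.n_cols, N = x.n_slices;
  const int Cout = w.n_rows, pad = (k - 1) / 2;
  cube y(L, Cout, N);
  if (k == 1) {
    for (int n = 0; n < N; ++n) y.slice(n) = x.slice(n) * w.t();
  } else {
    mat X(L, Cin * k);
    for (int n = 0; n < N; ++n) {
      im2col(x.slice(n), X, k, pad);
      y.slice(n) = X * w.t();
    }
  }
  if (b.n_elem) {
    rowvec bt = b.t();
    for (int n = 0; n < N; ++n) y.slice(n).each_row() += bt;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                   int k, bool has_bias, bool need_gx) {
  const int L = x.n_rows, Cin = x.n_cols, N = x.n_slices;
  const int Cout = w.n_rows, pad = (k - 1) / 2;
  mat gw(Cout, Cin * k, fill::zeros);
  vec gb(has_bias ? Cout : 0, fill::zeros);
  cube gx;
  if (need_gx) gx.zeros(L, Cin, N);
  if (k == 1) {
    for (int n = 0; n < N; ++n) {
      gw += gy.slice(n).t() * x.slice(n);
      if (need_gx) gx.slice(n) = gy.slice(n) * w;
    }
  } else {
    mat X(L, Cin * k);
    for (int n = 0; n < N; ++n) {
      im2col(x.slice(n), X, k, pad);
      gw += gy.slice(n).t() * X;
      if (need_gx) {
        mat G = gy.slice(n) * w; // (L x Cin*k)
        for (int c = 0; c < Cin; ++c) {
          for (int j = 0; j < k; ++j) {
            const int s = j - pad;
            const int lo = std::max(0, -s), hi = std::min(L, L - s);
            if (hi > lo)
              gx.slice(n).col(c).subvec(lo + s, hi - 1 + s) +=
                G.col(c * k + j).subvec(lo, hi - 1);
          }
        }
      }
    }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n) gb += sum(gy.slice(n), 0).t();
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// depthwise convolution, one kernel per channel; w: (k x C)
// [[Rcpp::export]]
arma::cube cpp_dwconv1d_fw(const arma::cube& x, const arma::mat& w) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int k = w.n_rows, pad = (k - 1) / 2;
  cube y(L, C, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(n).colptr(c);
      double* yc = y.slice(n).colptr(c);
      for (int j = 0; j < k; ++j) {
        const int s = j - pad;
        const double wj = w(j, c);
        const int lo = std::max(0, -s), hi = std::min(L, L - s);
        for (int i = lo; i < hi; ++i) yc[i] += wj * xc[i + s];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv1d_bw(const arma::cube& x, const arma::mat& w, const arma::cube& gy,
                     bool need_gx) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int k = w.n_rows, pad = (k - 1) / 2;
  mat gw(k, C, fill::zeros);
  cube gx;
  if (need_gx) gx.zeros(L, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(n).colptr(c);
      const double* gc = gy.slice(n).colptr(c);
      for (int j = 0; j < k; ++j) {
        const int s = j - pad;
        const int lo = std::max(0, -s), hi = std::min(L, L - s);
        double acc = 0.0;
        for (int i = lo; i < hi; ++i) acc += gc[i] * xc[i + s];
        gw(j, c) += acc;
      }
      if (need_gx) {
        double* gxc = gx.slice(n).colptr(c);
        for (int j = 0; j < k; ++j) {
          const int s = j - pad;
          const double wj = w(j, c);
          const int lo = std::max(0, -s), hi = std::min(L, L - s);
          for (int i = lo; i < hi; ++i) gxc[i + s] += wj * gc[i];
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// max pooling, kernel 3, stride 1, pad 1 (shape preserving); idx stores the
// chosen offset (-1, 0, +1) for the backward pass
// [[Rcpp::export]]
List cpp_maxpool3_fw(const arma::cube& x) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  cube y(L, C, N);
  cube idx(L, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(n).colptr(c);
      double* yc = y.slice(n).colptr(c);
      double* ic = idx.slice(n).colptr(c);
      for (int i = 0; i < L; ++i) {
        double best = xc[i]; int off = 0;
        if (i > 0 && xc[i - 1] > best) { best = xc[i - 1]; off = -1; }
        if (i < L - 1 && xc[i + 1] > best) { best = xc[i + 1]; off = 1; }
        yc[i] = best; ic[i] = off;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool3_bw(const arma::cube& idx, const arma::cube& gy) {
  const int L = gy.n_rows, C = gy.n_cols, N = gy.n_slices;
  cube gx(L, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.slice(n).colptr(c);
      const double* ic = idx.slice(n).colptr(c);
      double* xc = gx.slice(n).colptr(c);
      for (int i = 0; i < L; ++i) xc[i + (int)ic[i]] += gc[i];
    }
  return gx;
}

// average pooling with kernel == stride (non-overlapping windows)
// [[Rcpp::export]]
arma::cube cpp_avgpool_fw(const arma::cube& x, int k) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices, Lo = L / k;
  cube y(Lo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.slice(n).colptr(c);
      double* yc = y.slice(n).colptr(c);
      for (int o = 0; o < Lo; ++o) {
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += xc[o * k + j];
        yc[o] = s / k;
      }
    }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_avgpool_bw(const arma::cube& gy, int k, int L) {
  const int Lo = gy.n_rows, C = gy.n_cols, N = gy.n_slices;
  cube gx(L, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gc = gy.slice(n).colptr(c);
      double* xc = gx.slice(n).colptr(c);
      for (int o = 0; o < Lo; ++o)
        for (int j = 0; j < k; ++j) xc[o * k + j] += gc[o] / k;
    }
  return gx;
}

// batch normalization over (time, batch) per channel
// [[Rcpp::export]]
List cpp_bn_fw(const arma::cube& x, const arma::vec& gamma, const arma::vec& beta,
               const arma::vec& rmean, const arma::vec& rvar, double momentum,
               double eps, bool training) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const double M = (double)L * N;
  vec mu(C), var(C), rm = rmean, rv = rvar;
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.slice(n).colptr(c);
        for (int i = 0; i < L; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu(c) = s / M;
      var(c) = s2 / M - mu(c) * mu(c);
      if (var(c) < 0) var(c) = 0;
    }
    const double unbias = M > 1 ? M / (M - 1.0) : 1.0;
    rm = (1 - momentum) * rm + momentum * mu;
    rv = (1 - momentum) * rv + momentum * var * unbias;
  } else {
    mu = rmean; var = rvar;
  }
  vec invstd = 1.0 / sqrt(var + eps);
  cube y(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = gamma(c) * invstd(c), b0 = beta(c) - a * mu(c);
      const double* xc = x.slice(n).colptr(c);
      double* yc = y.slice(n).colptr(c);
      for (int i = 0; i < L; ++i) yc[i] = a * xc[i] + b0;
    }
  return List::create(_["y"] = y, _["mean"] = mu, _["invstd"] = invstd,
                      _["rmean"] = rm, _["rvar"] = rv);
}

// [[Rcpp::export]]
List cpp_bn_bw(const arma::cube& x, const arma::cube& gy, const arma::vec& gamma,
               const arma::vec& mu, const arma::vec& invstd, bool need_gx) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const double M = (double)L * N;
  vec ggamma(C, fill::zeros), gbeta(C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.slice(n).colptr(c);
      const double* gc = gy.slice(n).colptr(c);
      for (int i = 0; i < L; ++i) {
        sg += gc[i];
        sgx += gc[i] * (xc[i] - mu(c)) * invstd(c);
      }
    }
    gbeta(c) = sg; ggamma(c) = sgx;
  }
  cube gx;
  if (need_gx) {
    gx.set_size(L, C, N);
    for (int c = 0; c < C; ++c) {
      const double a = gamma(c) * invstd(c);
      const double mg = gbeta(c) / M, mgx = ggamma(c) / M;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.slice(n).colptr(c);
        const double* gc = gy.slice(n).colptr(c);
        double* oc = gx.slice(n).colptr(c);
        for (int i = 0; i < L; ++i) {
          const double xhat = (xc[i] - mu(c)) * invstd(c);
          oc[i] = a * (gc[i] - mg - xhat * mgx);
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
arma::cube cpp_relu_fw(const arma::cube& x) {
  cube y = x;
  y.for_each([](double& v) { if (v < 0) v = 0; });
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_relu_bw(const arma::cube& x, const arma::cube& gy) {
  cube gx = gy;
  const double* xp = x.memptr();
  double* gp = gx.memptr();
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) if (xp[i] <= 0) gp[i] = 0;
  return gx;
}

// global average pool over time: (L, C, N) -> (C, N)
// [[Rcpp::export]]
arma::mat cpp_gap_fw(const arma::cube& x) {
  const int C = x.n_cols, N = x.n_slices;
  mat y(C, N);
  for (int n = 0; n < N; ++n) y.col(n) = mean(x.slice(n), 0).t();
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_gap_bw(const arma::mat& gy, int L) {
  const int C = gy.n_rows, N = gy.n_cols;
  cube gx(L, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) gx.slice(n).col(c).fill(gy(c, n) / L);
  return gx;
}
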