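// Compiled kernels for the convolutional front of the network: temporal
// convolution (same padding, no activation), the first batch
// normalisation, and the depthwise spatial stage are fused into one
// forward and one backward call to keep passes over the largest
// intermediate (the [F1, C*S*N] temporal feature map) to a minimum.
// Layout convention matches the R driver: the flattened sample axis is
// (channel, time, batch) with channel fastest.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Build the im2col buffer for one padded sample: column tau holds the
// window Xpad[:, tau .. tau+S-1] flattened channel-fastest.
static void fill_xcol(const mat& Xslice, mat& Xpad, mat& Xcol,
                      const uword pl, const uword S) {
  const uword C = Xslice.n_rows;
  Xpad.cols(pl, pl + S - 1) = Xslice;
  for (uword tau = 0; tau < Xcol.n_cols; ++tau) {
    std::memcpy(Xcol.colptr(tau), Xpad.colptr(tau), C * S * sizeof(double));
  }
}

// Fused forward: temporal conv -> batch norm (batch statistics when
// training, running statistics otherwise) -> depthwise spatial conv.
// Xct [C, S, N]; Wt [T, F1]; Ws [C, D, F1].  Returns the spatial output
// Z2 [F1*D, S*N] (feature (f-1)*D + d), the raw temporal map Z1
// [F1, C*S*N] for the backward pass, and the normalisation statistics.
// [[Rcpp::export]]
Rcpp::List cpp_extract_fwd(const arma::cube& Xct, const arma::mat& Wt,
                           const arma::cube& Ws, const arma::vec& gamma,
                           const arma::vec& beta, const arma::vec& rmean,
                           const arma::vec& rvar, const bool training,
                           const double eps = 1e-5) {
  const uword C = Xct.n_rows, S = Xct.n_cols, N = Xct.n_slices;
  const uword T = Wt.n_rows, F1 = Wt.n_cols, D = Ws.n_cols;
  const uword pl = (T - 1) / 2, M = C * S * N, SN = S * N;

  Rcpp::NumericMatrix Z1r(F1, M);                // returned without copy
  mat Z1(Z1r.begin(), F1, M, false, true);
  {
    mat Xpad(C, S + T - 1, fill::zeros);
    mat Xcol(C * S, T);
    for (uword n = 0; n < N; ++n) {
      fill_xcol(Xct.slice(n), Xpad, Xcol, pl, S);
      Z1.cols(n * C * S, (n + 1) * C * S - 1) = (Xcol * Wt).t();
    }
  }

  vec mu(F1), v(F1);
  const double* z = Z1.memptr();
  if (training) {
    vec s1(F1, fill::zeros), s2(F1, fill::zeros);
    for (uword j = 0; j < F1 * M; j += F1)
      for (uword f = 0; f < F1; ++f) {
        const double x = z[j + f];
        s1[f] += x; s2[f] += x * x;
      }
    mu = s1 / double(M);
    v = s2 / double(M) - mu % mu;
    v.transform([](double x) { return x < 0 ? 0 : x; });
  } else {
    mu = rmean; v = rvar;
  }
  vec inv = 1.0 / sqrt(v + eps);

  // normalise row-by-row into per-feature buffers in one pass over Z1,
  // then one small GEMM per temporal kernel
  cube A(C * S, N, F1);                          // A(:, :, f) = map f
  for (uword j = 0; j < M; ++j) {
    const double* zc = z + j * F1;
    for (uword f = 0; f < F1; ++f) {
      A.slice(f)[j] = gamma[f] * ((zc[f] - mu[f]) * inv[f]) + beta[f];
    }
  }
  mat Z2(F1 * D, SN);
  for (uword f = 0; f < F1; ++f) {
    const mat Mf(A.slice(f).memptr(), C, SN, false, true);
    Z2.rows(f * D, (f + 1) * D - 1) = Ws.slice(f).t() * Mf;
  }
  return Rcpp::List::create(
      Rcpp::Named("Z2") = Z2, Rcpp::Named("Z1") = Z1r,
      Rcpp::Named("mu") = mu, Rcpp::Named("v") = v,
      Rcpp::Named("inv") = inv);
}

// Fused backward for the same three stages.  dZ2 is [F1*D, S*N]; the
// returned gradients cover the spatial kernels, the batch-norm affine
// pair and the temporal kernels.
// [[Rcpp::export]]
Rcpp::List cpp_extract_bwd(const arma::cube& Xct, const arma::mat& Z1,
                           const arma::vec& mu, const arma::vec& inv,
                           const arma::vec& gamma, const arma::vec& beta,
                           const arma::cube& Ws, const arma::mat& dZ2,
                           const int T) {
  const uword C = Xct.n_rows, S = Xct.n_cols, N = Xct.n_slices;
  const uword F1 = Z1.n_rows, D = Ws.n_cols;
  const uword pl = (T - 1) / 2, M = C * S * N, SN = S * N;
  const double* z = Z1.memptr();

  cube dWs(C, D, F1);
  mat xh(C * S, N);                              // xhat of one map
  mat Mf(C * S, N);
  vec sg(F1, fill::zeros), sb(F1, fill::zeros);
  mat dZ(F1, M);
  double* dz = dZ.memptr();

  for (uword f = 0; f < F1; ++f) {
    double* xp = xh.memptr();
    double* mp = Mf.memptr();
    for (uword j = 0; j < M; ++j) {
      const double h = (z[j * F1 + f] - mu[f]) * inv[f];
      xp[j] = h;
      mp[j] = gamma[f] * h + beta[f];
    }
    const mat dZf = dZ2.rows(f * D, (f + 1) * D - 1);   // [D, S*N]
    const mat MfM(mp, C, SN, false, true);
    dWs.slice(f) = MfM * dZf.t();
    mat dMf = Ws.slice(f) * dZf;                 // [C, S*N] = dA1 row f
    const double* dp = dMf.memptr();
    double s1 = 0, s2 = 0;
    for (uword j = 0; j < M; ++j) {
      s1 += dp[j];
      s2 += dp[j] * xp[j];
    }
    sb[f] = s1; sg[f] = s2;
    const double m1 = gamma[f] * s1 / double(M);
    const double m2 = gamma[f] * s2 / double(M);
    for (uword j = 0; j < M; ++j) {
      dz[j * F1 + f] = (gamma[f] * dp[j] - m1 - xp[j] * m2) * inv[f];
    }
  }

  mat dWt(T, F1, fill::zeros);
  {
    mat Xpad(C, S + T - 1, fill::zeros);
    mat Xcol(C * S, T);
    for (uword n = 0; n < N; ++n) {
      fill_xcol(Xct.slice(n), Xpad, Xcol, pl, S);
      dWt += Xcol.t() * dZ.cols(n * C * S, (n + 1) * C * S - 1).t();
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("dWt") = dWt, Rcpp::Named("dWs") = dWs,
      Rcpp::Named("dgamma") = sg, Rcpp::Named("dbeta") = sb);
}
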