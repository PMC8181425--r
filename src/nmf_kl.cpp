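// Multiplicative-update NMF minimising the generalized Kullback-Leibler
// divergence D(X || WH) = sum_ij [ X_ij log(X_ij/(WH)_ij) - X_ij + (WH)_ij ],
// with the 0*log(0) = 0 convention. The inner loop lives here because the
// consensus and jackknife machinery re-run it thousands of times; elementwise
// steps are fused (the objective is evaluated in the same pass that prepares
// the next update's X/WH ratio) and there are two GEMMs per iteration.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int max_iter, double tol, double eps, int window,
                      int stop_connectivity) {
  const uword m = X.n_rows, n = X.n_cols, k = W.n_cols;
  if (W.n_rows != m || H.n_cols != n || H.n_rows != k)
    Rcpp::stop("factor dimensions do not match X");
  const uword mn = m * n;

  double xsum = accu(X);
  double xlogx = 0.0;
  for (uword i = 0; i < mn; ++i) {
    double x = X(i);
    if (x > 0) xlogx += x * std::log(x);
  }

  mat WH = W * H;
  mat V(m, n);
  // one pass: V = X / max(WH, eps) and D(X || WH)
  auto ratio_and_divergence = [&]() {
    double s = 0.0, lp = 0.0;
    const double* x = X.memptr();
    const double* p = WH.memptr();
    double* v = V.memptr();
    for (uword i = 0; i < mn; ++i) {
      double pi = p[i] < eps ? eps : p[i];
      s += pi;
      if (x[i] > 0) lp += x[i] * std::log(pi);
      v[i] = x[i] / pi;
    }
    return xlogx - lp - xsum + s;
  };
  auto ratio_only = [&]() {
    const double* x = X.memptr();
    const double* p = WH.memptr();
    double* v = V.memptr();
    for (uword i = 0; i < mn; ++i)
      v[i] = x[i] / (p[i] < eps ? eps : p[i]);
  };

  std::vector<double> trace;
  trace.push_back(ratio_and_divergence()); // D at the initial W, H

  uvec assign(n), prev_assign(n, fill::zeros);
  int stable = 0;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // V already holds X/WH for the current W, H.
    // H_aj <- H_aj * [ W^T (X/WH) ]_aj / colsum(W)_a
    H %= (W.t() * V);
    H.each_col() /= clamp(sum(W, 0).t(), eps, datum::inf);
    H.transform([eps](double v) { return v < eps ? eps : v; });

    // W_ia <- W_ia * [ (X/WH) H^T ]_ia / rowsum(H)_a, with the fresh H
    WH = W * H;
    ratio_only();
    W %= (V * H.t());
    W.each_row() /= clamp(sum(H, 1).t(), eps, datum::inf);
    W.transform([eps](double v) { return v < eps ? eps : v; });

    WH = W * H;
    double d = ratio_and_divergence(); // also preps V for the next H update
    trace.push_back(d);

    if (iter >= window) {
      double d_old = trace[iter - window];
      // relative decrease over the window; the additive floor keeps the
      // stop rule meaningful when the divergence itself approaches zero
      if (d_old - d <= tol * (std::abs(d_old) + 1e-9)) {
        converged = true;
        break;
      }
    }
    if (stop_connectivity > 0) {
      for (uword j = 0; j < n; ++j)
        assign(j) = index_max(H.col(j));
      stable = all(assign == prev_assign) ? stable + 1 : 0;
      prev_assign = assign;
      if (stable >= stop_connectivity) {
        converged = true;
        break;
      }
    }
  }
  if (iter > max_iter) iter = max_iter;

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("divergence_trace") = trace,
      Rcpp::Named("n_iter") = iter,
      Rcpp::Named("converged") = converged);
}
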