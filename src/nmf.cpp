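#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lee-Seung multiplicative updates for the Frobenius NMF objective
// ||X - W H||_F^2. Updates keep W, H elementwise nonnegative; the RSS is
// nonincreasing across iterations. Stops when the relative RSS decrease
// falls below `tol` or after `max_iter` iterations.
// [[Rcpp::export]]
Rcpp::List nmf_multiplicative(const arma::mat& X, arma::mat W, arma::mat H,
                              int max_iter, double tol) {
  const double eps = 1e-12;
  double rss_prev = accu(square(X - W * H));
  double rss = rss_prev;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    H %= (W.t() * X) / (W.t() * W * H + eps);
    W %= (X * H.t()) / (W * H * H.t() + eps);
    rss = accu(square(X - W * H));
    if (rss_prev - rss <= tol * rss_prev) { break; }
    rss_prev = rss;
  }
  if (it > max_iter) it = max_iter;
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("rss") = rss,
                            Rcpp::Named("iterations") = it);
}
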