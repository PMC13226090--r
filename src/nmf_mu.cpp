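#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Multiplicative updates for the Frobenius NMF objective ||X - WH||_F^2
// (Lee & Seung). Initial W, H are supplied by the caller so that seeding
// stays under R's RNG. Objective is evaluated every `check_every`
// iterations through the trace identity
//   ||X - WH||^2 = ||X||^2 - 2 <W'X, H> + <W'W, HH'>
// which reuses the small k x n / k x k products and avoids forming WH.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every) {
  const double eps = 1e-10;
  const double sxx = arma::accu(arma::square(X));
  double obj_prev = arma::datum::inf;
  double obj = obj_prev;
  int iters = 0;
  bool converged = false;

  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    // H <- H * (W'X) / (W'W H)
    arma::mat WtW = W.t() * W;
    H %= (W.t() * X) / (WtW * H + eps);
    // W <- W * (XH') / (W HH')
    arma::mat HHt = H * H.t();
    W %= (X * H.t()) / (W * HHt + eps);

    if (it % check_every == 0 || it == max_iter) {
      arma::mat WtX = W.t() * X;
      double cross = arma::accu(WtX % H);
      double whwh = arma::accu((W.t() * W) % (H * H.t()));
      obj = sxx - 2.0 * cross + whwh;
      if (obj < 0) obj = 0;  // numerical guard near exact fits
      if (std::isfinite(obj_prev) &&
          (obj_prev - obj) <= tol * std::max(obj_prev, eps)) {
        converged = true;
        break;
      }
      obj_prev = obj;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective") = std::sqrt(obj),
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged);
}
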