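#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Lee-Seung multiplicative updates for min ||M - WC||_F with W, C >= 0.
// eps guards denominators against division by zero; it does not alter the
// fixed points for strictly positive factors. Returns the factors, the
// per-iteration Frobenius objective trace, and a convergence flag (relative
// objective change < tol before the iteration cap).
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
List nmf_mu_cpp(const arma::mat& M, arma::mat W, arma::mat C,
                int max_iter, double tol, double eps) {
  std::vector<double> trace;
  trace.reserve(max_iter);
  double obj_prev = arma::norm(M - W * C, "fro");
  bool converged = false;
  int used = 0;

  for (int it = 0; it < max_iter; ++it) {
    // C <- C .* (W'M) ./ (W'WC + eps)
    C %= (W.t() * M) / (W.t() * W * C + eps);
    // W <- W .* (MC') ./ (WCC' + eps)
    W %= (M * C.t()) / (W * C * C.t() + eps);

    double obj = arma::norm(M - W * C, "fro");
    trace.push_back(obj);
    used = it + 1;

    double denom = (obj_prev > 0.0) ? obj_prev : 1.0;
    if (std::fabs(obj_prev - obj) / denom < tol) {
      converged = true;
      break;
    }
    obj_prev = obj;
  }

  return List::create(
    _["w"] = W,
    _["c"] = C,
    _["objective"] = trace.empty() ? obj_prev : trace.back(),
    _["trace"] = trace,
    _["iterations"] = used,
    _["converged"] = converged);
}
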