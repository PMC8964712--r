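// Gaussian-observation hidden Markov model: EM (Baum-Welch), scaled
// forward/backward, and Viterbi decoding. Observations are rows of X
// (T x d); states are full-covariance multivariate Gaussians.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// Per-state Gaussian log densities, T x K. Cholesky-based; errors if a
// covariance is not positive-definite (caller is responsible for ridging).
static arma::mat gaussian_logdens(const arma::mat& X, const arma::mat& means,
                                  const arma::cube& covs) {
  const arma::uword T = X.n_rows, d = X.n_cols, K = means.n_rows;
  arma::mat logB(T, K);
  for (arma::uword k = 0; k < K; ++k) {
    arma::mat L;
    if (!arma::chol(L, covs.slice(k), "lower"))
      stop("covariance of state %d is not positive-definite", (int)(k + 1));
    arma::mat Xc = X.each_row() - means.row(k);
    // solve L Y' = Xc'  => quadratic form = rowSums(Y^2)
    arma::mat Y = arma::solve(arma::trimatl(L), Xc.t());
    arma::rowvec quad = arma::sum(arma::square(Y), 0);
    double logdet = 2.0 * arma::accu(arma::log(L.diag()));
    logB.col(k) = (-0.5 * (d * LOG2PI + logdet + quad.t()));
  }
  return logB;
}

// Scaled forward pass. Returns log-likelihood; optionally keeps alpha and
// scaling constants for the backward pass.
static double forward_scaled(const arma::mat& logB, const arma::mat& A,
                             const arma::vec& pi0, arma::mat* alpha_out,
                             arma::vec* logc_out, arma::mat* B_out,
                             arma::vec* m_out) {
  const arma::uword T = logB.n_rows, K = logB.n_cols;
  arma::vec m = arma::max(logB, 1);
  arma::mat B = arma::exp(logB.each_col() - m);
  arma::mat alpha(T, K);
  arma::vec logc(T);
  arma::rowvec a = pi0.t() % B.row(0);
  double c = arma::accu(a);
  if (c <= 0) stop("forward pass underflow at t = 1");
  a /= c;
  alpha.row(0) = a;
  logc(0) = std::log(c);
  arma::mat At = A.t();
  for (arma::uword t = 1; t < T; ++t) {
    a = (a * A) % B.row(t);
    c = arma::accu(a);
    if (c <= 0) stop("forward pass underflow at t = %d", (int)(t + 1));
    a /= c;
    alpha.row(t) = a;
    logc(t) = std::log(c);
  }
  double ll = arma::accu(logc) + arma::accu(m);
  if (alpha_out) *alpha_out = std::move(alpha);
  if (logc_out) *logc_out = std::move(logc);
  if (B_out) *B_out = std::move(B);
  if (m_out) *m_out = std::move(m);
  return ll;
}

// [[Rcpp::export]]
double cpp_forward_loglik(const arma::mat& X, const arma::mat& means,
                          const arma::cube& covs, const arma::mat& A,
                          const arma::vec& pi0) {
  arma::mat logB = gaussian_logdens(X, means, covs);
  return forward_scaled(logB, A, pi0, nullptr, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
arma::mat cpp_gaussian_logdens(const arma::mat& X, const arma::mat& means,
                               const arma::cube& covs) {
  return gaussian_logdens(X, means, covs);
}

// One full EM run from the supplied initial parameters.
// [[Rcpp::export]]
List cpp_hmm_em(const arma::mat& X, arma::mat means, arma::cube covs,
                arma::mat A, arma::vec pi0, int max_iter, double tol,
                double ridge, int min_iter) {
  const arma::uword T = X.n_rows, d = X.n_cols, K = means.n_rows;
  std::vector<double> trace;
  double ll_prev = -arma::datum::inf;
  bool converged = false;

  arma::mat alpha, B;
  arma::vec logc, m;
  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step
    arma::mat logB = gaussian_logdens(X, means, covs);
    double ll = forward_scaled(logB, A, pi0, &alpha, &logc, &B, &m);
    trace.push_back(ll);

    // backward pass with gamma and xi accumulation
    arma::mat gamma(T, K);
    arma::mat xi_sum(K, K, arma::fill::zeros);
    arma::rowvec beta(K, arma::fill::ones);
    gamma.row(T - 1) = alpha.row(T - 1);
    for (arma::uword t = T - 1; t-- > 0; ) {
      arma::rowvec bb = B.row(t + 1) % beta;        // b_{t+1} * beta_{t+1}
      double ct1 = std::exp(logc(t + 1));
      xi_sum += (alpha.row(t).t() * bb) % A / ct1;
      beta = (A * bb.t()).t() / ct1;
      arma::rowvec g = alpha.row(t) % beta;
      gamma.row(t) = g / arma::accu(g);
    }

    // M-step
    pi0 = gamma.row(0).t();
    arma::vec rs = arma::sum(xi_sum, 1);
    for (arma::uword i = 0; i < K; ++i)
      if (rs(i) > 0) A.row(i) = xi_sum.row(i) / rs(i);
    arma::rowvec Nk = arma::sum(gamma, 0);
    means = (gamma.t() * X);
    means.each_col() /= Nk.t();
    for (arma::uword k = 0; k < K; ++k) {
      arma::mat Xc = X.each_row() - means.row(k);
      Xc.each_col() %= arma::sqrt(gamma.col(k));
      arma::mat S = (Xc.t() * Xc) / Nk(k);
      S = 0.5 * (S + S.t());
      S.diag() += ridge * arma::mean(S.diag());
      covs.slice(k) = S;
    }

    if (iter >= min_iter) {
      double gain = (ll - ll_prev) / (std::fabs(ll_prev) + 1e-12);
      if (gain < tol) { converged = true; break; }
    }
    ll_prev = ll;
  }

  return List::create(_["means"] = means, _["covariances"] = covs,
                      _["transition_matrix"] = A,
                      _["initial_distribution"] = pi0,
                      _["loglik_trace"] = trace,
                      _["converged"] = converged,
                      _["n_iter"] = (int)trace.size());
}

// Most probable joint state path; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const arma::mat& X, const arma::mat& means,
                          const arma::cube& covs, const arma::mat& A,
                          const arma::vec& pi0) {
  const arma::uword T = X.n_rows, K = means.n_rows;
  arma::mat logB = gaussian_logdens(X, means, covs);
  arma::mat logA(K, K);
  for (arma::uword i = 0; i < K; ++i)
    for (arma::uword j = 0; j < K; ++j)
      logA(i, j) = A(i, j) > 0 ? std::log(A(i, j)) : -arma::datum::inf;
  arma::vec logpi(K);
  for (arma::uword k = 0; k < K; ++k)
    logpi(k) = pi0(k) > 0 ? std::log(pi0(k)) : -arma::datum::inf;

  arma::Mat<int> psi(T, K);
  arma::rowvec delta = logpi.t() + logB.row(0);
  for (arma::uword t = 1; t < T; ++t) {
    arma::rowvec nd(K);
    for (arma::uword j = 0; j < K; ++j) {
      double best = -arma::datum::inf;
      int arg = 0;
      for (arma::uword i = 0; i < K; ++i) {
        double v = delta(i) + logA(i, j);
        if (v > best) { best = v; arg = (int)i; }  // strict: lowest i wins ties
      }
      nd(j) = best + logB(t, j);
      psi(t, j) = arg;
    }
    delta = nd;
  }
  IntegerVector path(T);
  int s = (int)arma::index_max(delta);  // index_max returns first max
  path[T - 1] = s + 1;
  for (arma::uword t = T - 1; t-- > 0; ) {
    s = psi(t + 1, s);
    path[t] = s + 1;
  }
  return path;
}

// First-order Markov chain driven by pre-drawn uniforms (RNG stays in R).
// cumA: K x K row-wise cumulative transition probabilities.
// [[Rcpp::export]]
IntegerVector cpp_markov_chain(const arma::mat& cumA, const arma::vec& cum_init,
                               const arma::vec& u) {
  const arma::uword T = u.n_elem, K = cumA.n_rows;
  IntegerVector out(T);
  arma::uword s = 0;
  while (s < K - 1 && u(0) > cum_init(s)) ++s;
  out[0] = (int)s + 1;
  for (arma::uword t = 1; t < T; ++t) {
    arma::uword j = 0;
    while (j < K - 1 && u(t) > cumA(s, j)) ++j;
    s = j;
    out[t] = (int)s + 1;
  }
  return out;
}
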