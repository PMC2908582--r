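#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Objective: (1/n) ||y - X b||^2 + tau ||b||_1 + mu ||b||_2^2
static double l1l2_objective(const mat& X, const vec& y, const vec& b,
                             double tau, double mu) {
  vec r = y - X * b;
  return dot(r, r) / X.n_rows + tau * norm(b, 1) + mu * dot(b, b);
}

// One damped ISTA sweep:
//   b <- (1 + mu/sigma)^{-1} * soft(b + X'(y - X b) / (n sigma), tau / (2 sigma))
// sigma is the largest squared singular value of X / sqrt(n), i.e. half the
// Lipschitz constant of the least-squares gradient; the l2 term is handled
// exactly in the proximal step, giving linear convergence for mu > 0.
static void ista_step(const mat& X, const mat& Xt, const vec& y, vec& b,
                      double tau, double mu, double sigma) {
  const double n = X.n_rows;
  vec z = b + Xt * (y - X * b) / (n * sigma);
  const double thr = tau / (2.0 * sigma);
  const double damp = 1.0 / (1.0 + mu / sigma);
  for (uword j = 0; j < z.n_elem; ++j) {
    double v = std::fabs(z(j)) - thr;
    z(j) = v > 0.0 ? damp * (z(j) > 0 ? v : -v) : 0.0;
  }
  b = z;
}

// [[Rcpp::export(name = ".ista_solve_cpp")]]
Rcpp::List ista_solve_cpp(const arma::mat& X, const arma::vec& y, double tau,
                          double mu, double sigma, double tol, int max_iter,
                          const arma::vec& beta0, bool trace) {
  mat Xt = X.t();
  vec b = beta0;
  std::vector<double> obj;
  if (trace) obj.push_back(l1l2_objective(X, y, b, tau, mu));
  bool converged = false;
  int it = 0;
  for (; it < max_iter; ++it) {
    vec b_old = b;
    ista_step(X, Xt, y, b, tau, mu, sigma);
    if (trace) obj.push_back(l1l2_objective(X, y, b, tau, mu));
    double delta = norm(b - b_old, "inf");
    if (delta < tol * std::max(1.0, norm(b, "inf"))) {
      converged = true;
      ++it;
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = b,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = it,
      Rcpp::Named("objective") = obj);
}

// Held-out classification errors of the ridge-de-biased classifier for every
// column of a solution path. The ridge re-fit is evaluated in its dual form,
//   x'beta_s = (Z_s x_s)' (Z_s Z_s' + lambda I)^{-1} y,
// with the support Gram matrix and the test kernel vector updated
// incrementally along the (largely nested) path.
// [[Rcpp::export(name = ".path_holdout_cpp")]]
Rcpp::IntegerVector path_holdout_cpp(const arma::mat& betas,
                                     const arma::mat& Xs, const arma::vec& ytr,
                                     const arma::vec& xte, double yte,
                                     double lambda, double majority) {
  const uword n = Xs.n_rows, p = Xs.n_cols, T = betas.n_cols;
  Rcpp::IntegerVector errs(T);
  mat G(n, n, fill::zeros);
  vec v(n, fill::zeros);
  std::vector<char> in(p, 0);
  for (uword k = 0; k < T; ++k) {
    uword nsupp = 0;
    for (uword j = 0; j < p; ++j) {
      bool now = betas(j, k) != 0.0;
      if (now) ++nsupp;
      if (now && !in[j]) {
        G += Xs.col(j) * Xs.col(j).t();
        v += xte(j) * Xs.col(j);
        in[j] = 1;
      } else if (!now && in[j]) {
        G -= Xs.col(j) * Xs.col(j).t();
        v -= xte(j) * Xs.col(j);
        in[j] = 0;
      }
    }
    double pred;
    if (nsupp == 0) {
      pred = majority;
    } else {
      mat A = G;
      A.diag() += lambda;
      double score = dot(v, solve(A, ytr, solve_opts::likely_sympd));
      pred = score == 0.0 ? majority : (score > 0 ? 1.0 : -1.0);
    }
    errs[k] = (pred != yte) ? 1 : 0;
  }
  return errs;
}

// Warm-started solution path over a descending tau grid (shared mu).
// [[Rcpp::export(name = ".ista_path_cpp")]]
Rcpp::List ista_path_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::vec& taus, double mu, double sigma,
                         double tol, int max_iter) {
  const uword p = X.n_cols, T = taus.n_elem;
  mat Xt = X.t();
  mat betas(p, T, fill::zeros);
  ivec iters(T, fill::zeros);
  ivec conv(T, fill::zeros);
  vec b(p, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    bool converged = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      vec b_old = b;
      ista_step(X, Xt, y, b, taus(k), mu, sigma);
      double delta = norm(b - b_old, "inf");
      if (delta < tol * std::max(1.0, norm(b, "inf"))) {
        converged = true;
        ++it;
        break;
      }
    }
    betas.col(k) = b;
    iters(k) = it;
    conv(k) = converged ? 1 : 0;
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = betas,
      Rcpp::Named("converged") = conv,
      Rcpp::Named("iterations") = iters);
}
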