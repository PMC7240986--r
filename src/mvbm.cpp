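// Likelihood machinery for the bivariate Brownian-Motion model on a phylogeny.
//
// The 2n-dimensional observation vector y = (x1, x2) (trait-major stacking)
// is multivariate normal with mean D theta (D the 2n x 2 trait-indicator
// design) and covariance
//
//   Sigma = R (x) C + diag(se^2)
//
// where C is the n x n species covariance from the tree, R the 2 x 2
// evolutionary rate matrix and se the per-observation measurement error.
// theta is profiled out by GLS, which is exact ML because theta enters the
// mean only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// Build Sigma for given R. C is n x n, se2 a 2n vector of squared errors.
static mat build_sigma(const mat& C, const mat& R, const vec& se2) {
    const uword n = C.n_rows;
    mat S(2 * n, 2 * n);
    S.submat(0, 0, n - 1, n - 1) = R(0, 0) * C;
    S.submat(0, n, n - 1, 2 * n - 1) = R(0, 1) * C;
    S.submat(n, 0, 2 * n - 1, n - 1) = R(1, 0) * C;
    S.submat(n, n, 2 * n - 1, 2 * n - 1) = R(1, 1) * C;
    S.diag() += se2;
    return S;
}

// Profiled log-likelihood; theta_out receives the GLS root state.
// Returns -datum::inf if Sigma is not positive definite.
static double profiled_loglik(const mat& C, const mat& R, const vec& se2,
                              const vec& y, vec& theta_out) {
    const uword n = C.n_rows;
    mat S = build_sigma(C, R, se2);
    mat L;
    if (!chol(L, S, "lower")) return -datum::inf;

    mat D(2 * n, 2, fill::zeros);
    D.submat(0, 0, n - 1, 0).ones();
    D.submat(n, 1, 2 * n - 1, 1).ones();

    // whiten: Lz = y, LW = D (triangular solves are backward stable; skip
    // the rcond estimate, which trips on the large dynamic range of Sigma
    // during optimization)
    vec z = solve(trimatl(L), y, solve_opts::fast + solve_opts::no_approx);
    mat W = solve(trimatl(L), D, solve_opts::fast + solve_opts::no_approx);

    mat XtX = W.t() * W;           // D' Sigma^-1 D (2 x 2)
    vec Xty = W.t() * z;
    double det = XtX(0, 0) * XtX(1, 1) - XtX(0, 1) * XtX(1, 0);
    if (det <= 0 || !std::isfinite(det)) return -datum::inf;
    vec theta(2);
    theta(0) = (XtX(1, 1) * Xty(0) - XtX(0, 1) * Xty(1)) / det;
    theta(1) = (XtX(0, 0) * Xty(1) - XtX(1, 0) * Xty(0)) / det;
    theta_out = theta;

    vec r = z - W * theta;
    double logdet = 2.0 * sum(log(L.diag()));
    double quad = dot(r, r);
    return -0.5 * (2.0 * n * LOG2PI + logdet + quad);
}

static mat rate_from_par(double a, double b, double z) {
    double r11 = std::exp(a), r22 = std::exp(b);
    double rho = std::tanh(z);
    mat R(2, 2);
    R(0, 0) = r11;
    R(1, 1) = r22;
    R(0, 1) = R(1, 0) = rho * std::sqrt(r11 * r22);
    return R;
}

// [[Rcpp::export(name = ".mvbm_nll")]]
double mvbm_nll(const arma::vec& par, const arma::mat& C, const arma::vec& y,
                const arma::vec& se2, bool constrained) {
    double z = constrained ? 0.0 : par(2);
    mat R = rate_from_par(par(0), par(1), z);
    vec theta;
    double ll = profiled_loglik(C, R, se2, y, theta);
    if (!std::isfinite(ll)) return 1e10;
    return -ll;
}

// [[Rcpp::export(name = ".mvbm_eval")]]
Rcpp::List mvbm_eval(const arma::vec& par, const arma::mat& C,
                     const arma::vec& y, const arma::vec& se2,
                     bool constrained) {
    double z = constrained ? 0.0 : par(2);
    mat R = rate_from_par(par(0), par(1), z);
    vec theta;
    double ll = profiled_loglik(C, R, se2, y, theta);
    return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                              Rcpp::Named("theta") = theta,
                              Rcpp::Named("R") = R);
}

// Direct log-density for arbitrary theta/R (the exported reference path
// calls this only for cross-checks; see mvbm_loglik in R).
// [[Rcpp::export(name = ".mvbm_loglik_at")]]
double mvbm_loglik_at(const arma::mat& C, const arma::vec& y,
                      const arma::vec& se2, const arma::vec& theta,
                      const arma::mat& R) {
    const uword n = C.n_rows;
    mat S = build_sigma(C, R, se2);
    mat L;
    if (!chol(L, S, "lower")) Rcpp::stop("covariance matrix not positive definite");
    vec mu(2 * n);
    mu.subvec(0, n - 1).fill(theta(0));
    mu.subvec(n, 2 * n - 1).fill(theta(1));
    vec r = solve(trimatl(L), y - mu,
                  solve_opts::fast + solve_opts::no_approx);
    double logdet = 2.0 * sum(log(L.diag()));
    return -0.5 * (2.0 * n * LOG2PI + logdet + dot(r, r));
}
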