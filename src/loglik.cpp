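#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// Gaussian log-density of a residual vector r with covariance S.
// Returns -Inf when S is not positive definite so the optimizer backs off.
static double mvn_logdens(const vec &r, mat &S) {
  if (!S.is_finite() || !r.is_finite()) return -datum::inf;
  mat L;
  if (!chol(L, S, "lower")) return -datum::inf;
  if (L.diag().min() <= 0) return -datum::inf;
  vec w = solve(trimatl(L), r);
  double ldet = 2.0 * sum(log(L.diag()));
  return -0.5 * ((double)r.n_elem * LOG2PI + ldet + dot(w, w));
}

// Full-information log-likelihood of the phenotypic latent growth model.
// Persons are independent; person p occupies observations ptr[p]..ptr[p+1]-1
// (0-based, ptr has length n_persons+1).  Per observation j the random-effect
// design row is (1, f_j); Sigma = Z G Z' + diag(sig2).
// [[Rcpp::export]]
double lgm_loglik_cpp(const arma::vec &y, const arma::vec &f,
                      const arma::ivec &ptr, const arma::vec &mu,
                      const arma::mat &G, const arma::vec &sig2) {
  const int n = ptr.n_elem - 1;
  double ll = 0.0;
  for (int p = 0; p < n; ++p) {
    const int a = ptr[p], b = ptr[p + 1], k = b - a;
    if (k <= 0) continue;
    mat Z(k, 2);
    for (int j = 0; j < k; ++j) { Z(j, 0) = 1.0; Z(j, 1) = f[a + j]; }
    mat S = Z * G * Z.t();
    for (int j = 0; j < k; ++j) S(j, j) += sig2[a + j];
    vec r = y.subvec(a, b - 1) - mu.subvec(a, b - 1);
    double lp = mvn_logdens(r, S);
    if (!std::isfinite(lp)) return -datum::inf;
    ll += lp;
  }
  return ll;
}

// Twin-pair log-likelihood for the bivariate ACE growth model.
// Pair p occupies observations ptr[p]..ptr[p+1]-1; `twin` (0/1) labels which
// member each observation belongs to.  Within-twin covariance uses A+C+E,
// cross-twin uses kappa*A + C (kappa = 1 MZ, 0.5 DZ); the measurement
// residual sig2 is twin-specific white noise.  Singletons (all obs one twin)
// are handled by the same expression.
// [[Rcpp::export]]
double ace_loglik_cpp(const arma::vec &y, const arma::vec &f,
                      const arma::ivec &ptr, const arma::ivec &twin,
                      const arma::vec &mu,
                      const arma::mat &A, const arma::mat &C,
                      const arma::mat &E, const arma::vec &kappa,
                      const arma::vec &sig2) {
  const int n = ptr.n_elem - 1;
  mat W = A + C + E;  // within-twin latent covariance
  double ll = 0.0;
  for (int p = 0; p < n; ++p) {
    const int a = ptr[p], b = ptr[p + 1], k = b - a;
    if (k <= 0) continue;
    mat X = kappa[p] * A + C;  // cross-twin latent covariance
    mat S(k, k);
    for (int j = 0; j < k; ++j) {
      const double fj = f[a + j];
      for (int l = j; l < k; ++l) {
        const double fl = f[a + l];
        const mat &B = (twin[a + j] == twin[a + l]) ? W : X;
        double v = B(0, 0) + fj * B(1, 0) + fl * B(0, 1) + fj * fl * B(1, 1);
        S(j, l) = v;
        S(l, j) = v;
      }
      S(j, j) += sig2[a + j];
    }
    vec r = y.subvec(a, b - 1) - mu.subvec(a, b - 1);
    double lp = mvn_logdens(r, S);
    if (!std::isfinite(lp)) return -datum::inf;
    ll += lp;
  }
  return ll;
}
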