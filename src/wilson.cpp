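// Wilson's iterative minimum-phase spectral matrix factorization,
// S(f) = psi(f) psi(f)^H with psi causal and invertible, used by the
// nonparametric Granger-causality estimator. Compiled because the
// iteration performs O(maxit * nfft) small dense solves, which sit in
// the inner loop of permutation tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Causal ("plus") projection of g across the frequency circle:
// transform to the lag domain, keep nonnegative lags up to nfft/2
// (the shared Nyquist lag halved, as in the scalar cepstral method);
// the upper-triangular split of the zero-lag term happens at the
// matrix level in the caller.
static void plus_operator(cx_cube& g, uword keep) {
  const uword m = g.n_rows, nf = g.n_slices;
  cx_vec v(nf);
  for (uword i = 0; i < m; ++i) {
    for (uword j = 0; j < m; ++j) {
      for (uword k = 0; k < nf; ++k) v(k) = g(i, j, k);
      cx_vec lam = ifft(v);
      if (keep < nf) lam(keep) *= 0.5;
      for (uword k = keep + 1; k < nf; ++k) lam(k) = cx_double(0.0, 0.0);
      cx_vec back = fft(lam);
      for (uword k = 0; k < nf; ++k) g(i, j, k) = back(k);
    }
  }
}

// [[Rcpp::export]]
Rcpp::List wilson_factor_cpp(arma::cx_cube S, double tol, int maxit) {
  const uword m = S.n_rows, nf = S.n_slices;
  const uword keep = nf / 2;

  cx_mat gamma0(m, m, fill::zeros);
  for (uword k = 0; k < nf; ++k) gamma0 += S.slice(k);
  gamma0 /= static_cast<double>(nf);
  mat g0 = real(gamma0);
  g0 = 0.5 * (g0 + g0.t());
  mat R;
  if (!chol(R, g0)) {
    double ridge = trace(g0) / m * 1e-8 + 1e-12;
    g0.diag() += ridge;
    if (!chol(R, g0)) Rcpp::stop("lag-zero covariance is not positive definite");
  }
  cx_mat psi0 = conv_to<cx_mat>::from(R);

  cx_cube psi(m, m, nf);
  for (uword k = 0; k < nf; ++k) psi.slice(k) = psi0;

  cx_cube g(m, m, nf);
  cx_mat I = eye<cx_mat>(m, m);
  double relerr = datum::inf;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    for (uword k = 0; k < nf; ++k) {
      cx_mat Pinv = inv(psi.slice(k));
      g.slice(k) = Pinv * S.slice(k) * Pinv.t() + I;  // .t() is Hermitian here
    }
    // causal part with upper-triangular zero-lag correction
    // lag-domain zero-lag term of g:
    cx_mat lag0(m, m, fill::zeros);
    for (uword k = 0; k < nf; ++k) lag0 += g.slice(k);
    lag0 /= static_cast<double>(nf);
    plus_operator(g, keep);
    // plus_operator kept the full zero-lag term; replace it by the
    // upper-triangular half so that gp + gp^H = g on the circle
    cx_mat beta0 = 0.5 * lag0;
    cx_mat delta = trimatu(beta0) - lag0;  // correction added at every f
    for (uword k = 0; k < nf; ++k) g.slice(k) += delta;

    double num = 0.0, den = 0.0;
    for (uword k = 0; k < nf; ++k) {
      cx_mat psinew = psi.slice(k) * g.slice(k);
      num = std::max(num, abs(psinew - psi.slice(k)).max());
      den = std::max(den, abs(psi.slice(k)).max());
      psi.slice(k) = psinew;
    }
    relerr = num / std::max(den, 1e-300);
    if (relerr < tol) { ++it; break; }
  }

  // zero-lag coefficient and innovation covariance
  cx_mat A0c(m, m, fill::zeros);
  for (uword k = 0; k < nf; ++k) A0c += psi.slice(k);
  A0c /= static_cast<double>(nf);
  mat A0 = real(A0c);

  return Rcpp::List::create(
    Rcpp::Named("psi") = psi,
    Rcpp::Named("A0") = A0,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("relerr") = relerr);
}
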