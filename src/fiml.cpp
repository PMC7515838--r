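// Full-information maximum likelihood for RAM-parameterized structural
// equation models, grouped by missingness pattern, with analytic gradients.
//
// RAM form: v = A v + u,  E[u] = M, Cov(u) = S, observed rows selected by
// `obs`.  Implied moments over all t variables:
//   mu_full = B M,  V = B S B'   with  B = (I - A)^{-1}.
// The log-likelihood sums, over missingness patterns k with observed column
// set o_k, the MVN log-density of each row's observed sub-vector under
// (mu[o_k], Sigma[o_k, o_k]).
//
// Gradient identities (G = scatter of per-pattern weight matrices
// Omega_k = Sig_k^-1 W_k Sig_k^-1 - n_k Sig_k^-1, g = scatter of
// Sig_k^-1 s_k, with W_k the residual scatter and s_k the residual sum):
//   dl/dS    = B' G B          (off-diagonal cells; halve the diagonal)
//   dl/dA    = B' G V + (B' g) mu_full'
//   dl/dM    = B' g
// A singular pattern covariance returns ok = false; the caller applies an
// optimizer-safe penalty.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export]]
List fiml_ram_cpp(const arma::mat& A, const arma::mat& S, const arma::vec& M,
                  const arma::uvec& obs, const List& patterns, bool grad) {
  const uword t = A.n_rows;
  mat B;
  bool okB = inv(B, eye(t, t) - A);
  if (!okB) return List::create(_["ok"] = false, _["ll"] = R_NegInf);

  mat V = B * S * B.t();
  vec mu_full = B * M;
  mat Sigma = V.submat(obs, obs);
  vec mu = mu_full.elem(obs);

  double ll = 0.0;
  mat Gfull(t, t, fill::zeros);
  vec gvec(t, fill::zeros);

  const int K = patterns.size();
  for (int k = 0; k < K; ++k) {
    List pk = patterns[k];
    uvec idx = as<uvec>(pk["cols"]);      // 0-based into the observed set
    mat Y = as<mat>(pk["Y"]);             // n_k x p_k
    const uword nk = Y.n_rows, p = idx.n_elem;
    if (nk == 0 || p == 0) continue;

    mat Sig_k = Sigma.submat(idx, idx);
    vec mu_k = mu.elem(idx);
    mat L;
    if (!chol(L, Sig_k, "lower"))
      return List::create(_["ok"] = false, _["ll"] = R_NegInf);

    mat R = Y.each_row() - mu_k.t();      // n_k x p residuals
    mat Z = solve(trimatl(L), R.t());     // p x n_k
    double logdet = 2.0 * accu(log(L.diag()));
    ll += -0.5 * (double)nk * ((double)p * LOG2PI + logdet) - 0.5 * accu(Z % Z);

    if (grad) {
      mat Sig_inv = inv_sympd(Sig_k);
      mat W = R.t() * R;
      vec s = sum(R, 0).t();
      mat Omega = Sig_inv * W * Sig_inv - (double)nk * Sig_inv;
      uvec gidx = obs.elem(idx);          // global variable indices
      Gfull.submat(gidx, gidx) += Omega;
      gvec.elem(gidx) += Sig_inv * s;
    }
  }

  if (!grad) return List::create(_["ok"] = true, _["ll"] = ll);

  mat BtG = B.t() * Gfull;
  mat dS = BtG * B;
  dS.diag() *= 0.5;
  vec Btg = B.t() * gvec;
  mat dA = BtG * V + Btg * mu_full.t();
  return List::create(_["ok"] = true, _["ll"] = ll,
                      _["dA"] = dA, _["dS"] = dS, _["dM"] = Btg);
}

// Regression-method factor scores under missing data.  For each pattern the
// joint normality of (latents eta, observed y_o) gives
//   E[eta | y_o] = mu_eta + C_o Sigma_o^{-1} (y_o - mu_o)
// with C_o = Cov(eta, y_o) read off the full RAM-implied covariance V.
// `lat` indexes the latent variables whose scores are wanted.
// [[Rcpp::export]]
List factor_scores_cpp(const arma::mat& A, const arma::mat& S, const arma::vec& M,
                       const arma::uvec& obs, const arma::uvec& lat,
                       const List& patterns) {
  const uword t = A.n_rows;
  mat B = inv(eye(t, t) - A);
  mat V = B * S * B.t();
  vec mu_full = B * M;
  const uword q = lat.n_elem;

  const int K = patterns.size();
  List out(K);
  for (int k = 0; k < K; ++k) {
    List pk = patterns[k];
    uvec idx = as<uvec>(pk["cols"]);
    mat Y = as<mat>(pk["Y"]);
    uvec gidx = obs.elem(idx);
    mat Sig_k = V.submat(gidx, gidx);
    mat C = V.submat(lat, gidx);                   // q x p
    vec mu_o = mu_full.elem(gidx);
    mat R = Y.each_row() - mu_o.t();               // n_k x p
    mat coef = solve(Sig_k, C.t());                // p x q
    mat scores = R * coef;                         // n_k x q
    scores.each_row() += mu_full.elem(lat).t();
    out[k] = scores;
  }
  return out;
}
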