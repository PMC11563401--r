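// Inner loops of the multitrait Gibbs samplers. All random numbers come
// from R's RNG (RNGScope via Rcpp attributes), so set.seed() in R makes
// chains fully reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec rnormVec(int k) {
  arma::vec z(k);
  for (int i = 0; i < k; ++i) z[i] = norm_rand();
  return z;
}

// One full sweep over markers for the multitrait ridge (BRR) model.
// Returns the updated residual matrix E (n x t) and effect matrix B.
// [[Rcpp::export(name = ".brrSweep")]]
List brrSweep(arma::mat E, const arma::mat& X, arma::mat B,
              const arma::mat& R0inv, const arma::mat& SigmaBinv,
              const arma::vec& xtx) {
  const int m = X.n_cols;
  const int t = B.n_cols;
  for (int j = 0; j < m; ++j) {
    arma::vec xj = X.col(j);
    arma::rowvec bOld = B.row(j);
    E += xj * bOld; // remove marker j's contribution
    arma::vec rhs = R0inv * (E.t() * xj);
    arma::mat prec = xtx[j] * R0inv + SigmaBinv;
    arma::mat cov = arma::inv_sympd(prec);
    arma::vec mean = cov * rhs;
    arma::mat cl = arma::chol(cov, "lower");
    arma::vec bNew = mean + cl * rnormVec(t);
    B.row(j) = bNew.t();
    E -= xj * bNew.t();
  }
  return List::create(Named("E") = E, Named("B") = B);
}

// One full sweep over (marker, trait) cells for the multitrait
// spike-and-slab model: Bernoulli inclusion indicator per cell, scalar
// slab draw conditional on everything else (exact under full R0).
// Returns the updated E, B and inclusion indicators delta.
// [[Rcpp::export(name = ".ssSweep")]]
List ssSweep(arma::mat E, const arma::mat& X, arma::mat B,
             arma::imat delta, const arma::mat& R0inv,
             const arma::vec& slabVar, const arma::vec& logitPi,
             const arma::vec& xtx) {
  const int m = X.n_cols;
  const int t = B.n_cols;
  for (int j = 0; j < m; ++j) {
    arma::vec xj = X.col(j);
    for (int s = 0; s < t; ++s) {
      double bOld = B(j, s);
      if (bOld != 0.0) E.col(s) += xj * bOld;
      // scalar conditional: precision and mean under the slab
      double prec = xtx[j] * R0inv(s, s) + 1.0 / slabVar[s];
      double v = 1.0 / prec;
      double rhs = arma::dot(xj, E * R0inv.col(s));
      double mval = v * rhs;
      double logBF = 0.5 * std::log(v / slabVar[s]) + 0.5 * mval * mval / v;
      double logOdds = logitPi[s] + logBF;
      double pIncl = 1.0 / (1.0 + std::exp(-logOdds));
      double u = unif_rand();
      if (u < pIncl) {
        double bNew = mval + std::sqrt(v) * norm_rand();
        B(j, s) = bNew;
        delta(j, s) = 1;
        E.col(s) -= xj * bNew;
      } else {
        B(j, s) = 0.0;
        delta(j, s) = 0;
      }
    }
  }
  return List::create(Named("E") = E, Named("B") = B, Named("delta") = delta);
}

// One update of a kernel random-effect matrix in its eigenbasis: the
// posterior factorizes over eigencomponents i, each a t-variate normal
// with precision R0inv + SigmaKinv / d_i. Etil is the transformed
// residual (r x t) EXCLUDING this kernel's effect; returns the new
// transformed effect matrix Util (r x t).
// [[Rcpp::export(name = ".rkhsSweep")]]
arma::mat rkhsSweep(const arma::mat& Etil, const arma::vec& d,
                    const arma::mat& R0inv, const arma::mat& SigmaKinv) {
  const int r = Etil.n_rows;
  const int t = Etil.n_cols;
  arma::mat out(r, t);
  for (int i = 0; i < r; ++i) {
    arma::mat prec = R0inv + SigmaKinv / d[i];
    arma::mat cov = arma::inv_sympd(prec);
    arma::vec mean = cov * (R0inv * Etil.row(i).t());
    arma::mat cl = arma::chol(cov, "lower");
    out.row(i) = (mean + cl * rnormVec(t)).t();
  }
  return out;
}
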