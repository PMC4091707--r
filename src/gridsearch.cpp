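// Exhaustive log-likelihood scan over the (f0, beta, mu, nu) mesh for the
// Fermi-Dirac steady-state model P(E) = Q0(E) F(E)^nu / Z on a binned
// energy spectrum.  Sites enter through per-bin counts (energies are
// snapped to the spectrum grid upstream), so
//   lnL(theta) = nu * sum_b n_b lnF(E_b) - n * ln Z(theta),
//   Z = sum_b Q0_b F(E_b)^nu   (log-sum-exp).
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double ln_fd(double x, double f0) {
  // log(f0 + (1-f0) * logistic(-x)), stable in both tails
  if (f0 <= 0.0) {
    return (x > 0.0) ? (-x - std::log1p(std::exp(-x)))
                     : (-std::log1p(std::exp(x)));
  }
  double p = (x > 0.0) ? std::exp(-x) / (1.0 + std::exp(-x))
                       : 1.0 / (1.0 + std::exp(x));
  return std::log(f0 + (1.0 - f0) * p);
}

// [[Rcpp::export]]
List fd_grid_scan(NumericVector lnq, NumericVector ebin,
                  NumericVector nsite, double n_total,
                  NumericVector f0_grid, NumericVector beta_grid,
                  NumericVector mu_grid, NumericVector nu_grid) {
  const int B = lnq.size();
  const int nf = f0_grid.size(), nb = beta_grid.size();
  const int nm = mu_grid.size(), nn = nu_grid.size();
  std::vector<double> lnF(B), t(B);
  std::vector<int> pop;  // populated site bins
  for (int b = 0; b < B; ++b) if (nsite[b] > 0) pop.push_back(b);

  double best = -std::numeric_limits<double>::infinity();
  int bi = -1, bj = -1, bk = -1, bl = -1;
  double bnu = R_PosInf, bbeta = R_PosInf, bmu = R_NegInf;

  for (int i = 0; i < nf; ++i) {
    const double f0 = f0_grid[i];
    for (int j = 0; j < nb; ++j) {
      const double beta = beta_grid[j];
      for (int k = 0; k < nm; ++k) {
        const double mu = mu_grid[k];
        for (int b = 0; b < B; ++b)
          lnF[b] = ln_fd(beta * (ebin[b] - mu), f0);
        double S = 0.0;
        for (size_t s = 0; s < pop.size(); ++s)
          S += nsite[pop[s]] * lnF[pop[s]];
        for (int l = 0; l < nn; ++l) {
          const double nu = nu_grid[l];
          double m = -std::numeric_limits<double>::infinity();
          for (int b = 0; b < B; ++b) {
            t[b] = lnq[b] + nu * lnF[b];
            if (t[b] > m) m = t[b];
          }
          double z = 0.0;
          for (int b = 0; b < B; ++b)
            if (std::isfinite(t[b])) z += std::exp(t[b] - m);
          const double lnZ = m + std::log(z);
          const double lnl = nu * S - n_total * lnZ;
          // ties broken toward smaller nu, then smaller beta, then larger mu
          bool take = lnl > best;
          if (!take && lnl == best) {
            if (nu < bnu) take = true;
            else if (nu == bnu && beta < bbeta) take = true;
            else if (nu == bnu && beta == bbeta && mu > bmu) take = true;
          }
          if (take) {
            best = lnl; bi = i; bj = j; bk = k; bl = l;
            bnu = nu; bbeta = beta; bmu = mu;
          }
        }
      }
    }
  }
  return List::create(_["lnL"] = best, _["i_f0"] = bi + 1,
                      _["i_beta"] = bj + 1, _["i_mu"] = bk + 1,
                      _["i_nu"] = bl + 1);
}
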