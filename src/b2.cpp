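// Composite likelihood ratio scan for balancing selection (B2-style).
//
// At a test position, each informative site (polymorphism with derived
// count k in 1..n-1, or substitution with k = n) contributes
//   ln[ (a_l h_beta(k_l) + (1 - a_l) g(k_l)) / g(k_l) ],
// where g is the genome-wide background spectrum, h_beta is the expected
// spectrum at a site balanced at frequency beta (binomial, renormalized
// over k = 1..n), and a_l = exp(-d_l / A) decays with physical distance.
// CLR = 2 * max over the (beta, A) grid, floored at 0 by the degenerate
// no-signal point (all a_l = 0).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
List b2_clr_cpp(NumericVector site_pos, IntegerVector site_k, int n,
                NumericVector g, NumericVector betas, NumericVector Avals,
                NumericVector test_pos) {
  int Lns = site_pos.size();
  int nb = betas.size(), na = Avals.size(), nt = test_pos.size();

  // h_beta(k) tables, k = 1..n (renormalized over 1..n)
  std::vector<std::vector<double>> h(nb, std::vector<double>(n + 1, 0.0));
  for (int b = 0; b < nb; ++b) {
    double tot = 0.0;
    for (int k = 1; k <= n; ++k) {
      double v = R::dbinom((double)k, (double)n, betas[b], 0);
      h[b][k] = v;
      tot += v;
    }
    for (int k = 1; k <= n; ++k) h[b][k] /= tot;
  }

  // per-site term: log(a h + (1-a) g) - log g = log1p(a (h/g - 1))
  std::vector<std::vector<double>> hg(nb, std::vector<double>(n + 1, 0.0));
  for (int b = 0; b < nb; ++b)
    for (int k = 1; k <= n; ++k) hg[b][k] = h[b][k] / g[k - 1] - 1.0;

  NumericVector clr(nt), beta_hat(nt), A_hat(nt);
  std::vector<double> alpha(Lns);

  for (int t = 0; t < nt; ++t) {
    double best = 0.0;  // no-signal point
    double bbeta = NA_REAL, bA = NA_REAL;
    for (int a = 0; a < na; ++a) {
      double A = Avals[a];
      // restrict to sites with non-negligible mixing weight
      double dmax = 40.0 * A;
      int lo = (int)(std::lower_bound(site_pos.begin(), site_pos.end(),
                                      test_pos[t] - dmax) - site_pos.begin());
      int hi = (int)(std::upper_bound(site_pos.begin(), site_pos.end(),
                                      test_pos[t] + dmax) - site_pos.begin());
      for (int l = lo; l < hi; ++l)
        alpha[l] = std::exp(-std::abs(site_pos[l] - test_pos[t]) / A);
      for (int b = 0; b < nb; ++b) {
        double ll = 0.0;
        const double* hgb = hg[b].data();
        for (int l = lo; l < hi; ++l)
          ll += std::log1p(alpha[l] * hgb[site_k[l]]);
        if (ll > best) { best = ll; bbeta = betas[b]; bA = A; }
      }
    }
    clr[t] = 2.0 * best;
    beta_hat[t] = bbeta;
    A_hat[t] = bA;
  }
  return List::create(_["clr"] = clr, _["beta_hat"] = beta_hat,
                      _["A_hat"] = A_hat);
}
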