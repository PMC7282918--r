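#include <Rcpp.h>
#include "pruning.h"
using namespace Rcpp;

// REML log-likelihood of Brownian motion with rate sigma2 and Gaussian tip
// noise sigma_tip on a rooted (possibly rescaled) tree.
//
// edge: ape edge matrix (1-based node ids, tips 1..n_tip, root n_tip + 1)
// postorder: 1-based row indices of `edge` in postorder
// [[Rcpp::export]]
double bm_reml_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                          IntegerVector postorder, int n_tip,
                          NumericVector tip_values, double sigma2,
                          double sigma_tip) {
  int E = edge.nrow();
  std::vector<int> par(E), chi(E), po(E);
  std::vector<double> evar(E);
  int maxnode = n_tip;
  for (int e = 0; e < E; ++e) {
    par[e] = edge(e, 0);
    chi[e] = edge(e, 1);
    if (par[e] > maxnode) maxnode = par[e];
    if (chi[e] > maxnode) maxnode = chi[e];
    evar[e] = sigma2 * edge_length[e];
  }
  for (int i = 0; i < E; ++i) po[i] = postorder[i] - 1;
  return bm_reml_core(par, chi, evar, po, n_tip, maxnode,
                      REAL(tip_values), sigma_tip * sigma_tip);
}

// Same pruning core but with per-edge variance accumulations given directly
// (used for rate-shift model likelihoods evaluated from R).
// [[Rcpp::export]]
double bm_reml_loglik_vars_cpp(IntegerMatrix edge, NumericVector edge_var,
                               IntegerVector postorder, int n_tip,
                               NumericVector tip_values) {
  int E = edge.nrow();
  std::vector<int> par(E), chi(E), po(E);
  std::vector<double> evar(E);
  int maxnode = n_tip;
  for (int e = 0; e < E; ++e) {
    par[e] = edge(e, 0);
    chi[e] = edge(e, 1);
    if (par[e] > maxnode) maxnode = par[e];
    if (chi[e] > maxnode) maxnode = chi[e];
    evar[e] = edge_var[e];
  }
  for (int i = 0; i < E; ++i) po[i] = postorder[i] - 1;
  return bm_reml_core(par, chi, evar, po, n_tip, maxnode,
                      REAL(tip_values), 0.0);
}
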