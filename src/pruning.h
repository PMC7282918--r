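#pragma once
#include <vector>
#include <cmath>
#include <limits>

// REML (phylogenetic independent contrasts) log-likelihood of a Gaussian
// trait on a rooted tree, polytomies allowed. Edges are visited in
// postorder (children before parents); evar[e] is the variance accumulated
// along edge e, tipvar is added at every tip. Children at a node are merged
// sequentially; the sum of contrast log-densities is order-invariant and
// equals the restricted likelihood with the root state profiled out.
inline double bm_reml_core(const std::vector<int>& par,
                           const std::vector<int>& chi,
                           const std::vector<double>& evar,
                           const std::vector<int>& postorder,
                           int n_tip, int n_node_total,
                           const double* tipval, double tipvar) {
  std::vector<double> x(n_node_total + 1, 0.0), v(n_node_total + 1, 0.0);
  std::vector<char> has(n_node_total + 1, 0);
  double ll = 0.0;
  const double LOG2PI = 1.837877066409345483560659472811;
  for (std::size_t idx = 0; idx < postorder.size(); ++idx) {
    int e = postorder[idx];
    int p = par[e], c = chi[e];
    double xc, vc;
    if (c <= n_tip) {
      xc = tipval[c - 1];
      vc = tipvar;
    } else {
      xc = x[c];
      vc = v[c];
    }
    vc += evar[e];
    if (!(vc > 0.0) && c > n_tip) {
      // an internal merge can legitimately carry zero variance only when the
      // edge itself has positive length; guard the degenerate case below
    }
    if (!has[p]) {
      x[p] = xc;
      v[p] = vc;
      has[p] = 1;
    } else {
      double vs = v[p] + vc;
      if (!(vs > 0.0)) return -std::numeric_limits<double>::infinity();
      double d = xc - x[p];
      ll += -0.5 * (LOG2PI + std::log(vs) + d * d / vs);
      x[p] = (vc * x[p] + v[p] * xc) / vs;
      v[p] = v[p] * vc / vs;
    }
  }
  return ll;
}
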