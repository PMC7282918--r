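#include <Rcpp.h>
#include "fft.h"
using namespace Rcpp;

typedef std::complex<double> cplx;

// Characteristic exponent psi(k) per unit (possibly rescaled) time for the
// symmetric, driftless Levy models. jump_type: 0 none (BM), 1 JN compound
// Poisson with Normal(0, delta^2) jumps, 2 symmetric centred NIG.
static inline double psi_eval(double k, int jump_type, double sigma2,
                              double lambda, double delta, double a_nig,
                              double d_nig) {
  double p = -0.5 * sigma2 * k * k;
  if (jump_type == 1) {
    p += lambda * (std::exp(-0.5 * delta * delta * k * k) - 1.0);
  } else if (jump_type == 2) {
    p += d_nig * (a_nig - std::sqrt(a_nig * a_nig + k * k));
  }
  return p;
}

// REML likelihood of tip data under a (possibly compound) Levy process,
// computed by pruning with node conditional densities represented on a
// regular grid of grid_n points starting at x0 with spacing dx. Branch
// propagation is circular convolution with the branch increment density,
// obtained by inverting exp(t * psi(k)) on the conjugate frequency grid.
// Tips enter through an exact spectral phase shift (no interpolation), with
// Normal(0, sigma_tip^2) observation noise folded into the branch transform,
// so sigma_tip = 0 is handled exactly. The root state is integrated against
// a flat prior, which for Gaussian models reproduces the contrasts REML
// value. Returns the log-likelihood; -Inf on numerical collapse.
// [[Rcpp::export]]
double levy_pruning_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                               IntegerVector postorder, int n_tip,
                               NumericVector tip_values, double sigma_tip,
                               int jump_type, double sigma2, double lambda,
                               double delta, double a_nig, double d_nig,
                               int grid_n, double x0, double dx,
                               double mass_tol) {
  const int E = edge.nrow();
  const int N = grid_n;
  int maxnode = n_tip;
  for (int e = 0; e < E; ++e) {
    if (edge(e, 0) > maxnode) maxnode = edge(e, 0);
    if (edge(e, 1) > maxnode) maxnode = edge(e, 1);
  }

  // frequency grid in DFT ("wrapped") order
  std::vector<double> kk(N);
  const double dk = 2.0 * M_PI / (N * dx);
  for (int m = 0; m < N; ++m) {
    int ms = (m < N / 2) ? m : m - N;
    kk[m] = dk * ms;
  }

  // messages per node: conditional density of the subtree data given the
  // node state, evaluated on the grid; log-scale factors carried separately
  std::vector<std::vector<double> > msg(maxnode + 1);
  std::vector<double> lsc(maxnode + 1, 0.0);
  std::vector<char> has(maxnode + 1, 0);

  const double st2 = sigma_tip * sigma_tip;
  std::vector<cplx> work(N);
  int root = n_tip + 1;

  for (int idx = 0; idx < E; ++idx) {
    int e = postorder[idx] - 1;
    int p = edge(e, 0), c = edge(e, 1);
    double t = edge_length[e];

    // increment CF over this branch (real, positive: symmetric driftless)
    std::vector<double> phi(N);
    for (int m = 0; m < N; ++m)
      phi[m] = std::exp(t * psi_eval(kk[m], jump_type, sigma2, lambda, delta,
                                     a_nig, d_nig));

    std::vector<double> out(N);
    if (c <= n_tip) {
      // tip: message is q(x_obs - s), q = branch density + tip noise; place
      // the observation exactly via a spectral phase factor
      double shift = tip_values[c - 1] - x0;
      for (int m = 0; m < N; ++m) {
        double amp = phi[m] * std::exp(-0.5 * st2 * kk[m] * kk[m]);
        double ang = -kk[m] * shift;
        work[m] = cplx(amp * std::cos(ang), amp * std::sin(ang));
      }
      fft_radix2(work, true);
      // keep the signed values: small negative ringing from the spectral
      // representation must be allowed to cancel, not be rectified
      for (int j = 0; j < N; ++j) out[j] = work[j].real() / dx;
    } else {
      if (!has[c]) return R_NegInf;  // should not happen with valid postorder
      for (int j = 0; j < N; ++j) work[j] = cplx(msg[c][j], 0.0);
      fft_radix2(work, false);
      for (int m = 0; m < N; ++m) work[m] *= phi[m];
      fft_radix2(work, true);
      for (int j = 0; j < N; ++j) out[j] = work[j].real();
    }

    // wrap-around guard: the branch increment density must be negligible in
    // the outer 5% of the displacement range
    if (mass_tol > 0.0) {
      std::vector<cplx> pw(N);
      for (int m = 0; m < N; ++m) pw[m] = cplx(phi[m], 0.0);
      fft_radix2(pw, true);
      double tail = 0.0, tot = 0.0;
      int edge_n = N / 20;
      for (int j = 0; j < N; ++j) {
        double pv = std::fabs(pw[j].real());
        tot += pv;
        // wrapped index j corresponds to displacement j*dx (j < N/2) or
        // (j - N)*dx; the extreme displacements sit around j = N/2
        if (j >= N / 2 - edge_n && j < N / 2 + edge_n) tail += pv;
      }
      if (tot > 0.0 && tail / tot > mass_tol)
        stop("branch increment density leaks %.2g of its mass outside the "
             "grid; enlarge the grid extent (padding) or resolution",
             tail / tot);
    }

    // multiply into the parent accumulator with rescaling
    double lc = (c <= n_tip) ? 0.0 : lsc[c];
    if (!has[p]) {
      msg[p] = out;
      lsc[p] = lc;
      has[p] = 1;
    } else {
      double mx = 0.0;
      for (int j = 0; j < N; ++j) {
        msg[p][j] *= out[j];
        double av = std::fabs(msg[p][j]);
        if (av > mx) mx = av;
      }
      if (!(mx > 0.0)) return R_NegInf;
      for (int j = 0; j < N; ++j) msg[p][j] /= mx;
      lsc[p] += lc + std::log(mx);
    }
  }

  if (!has[root]) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < N; ++j) s += msg[root][j];
  s *= dx;
  if (!(s > 0.0) || !std::isfinite(s)) return R_NegInf;
  return std::log(s) + lsc[root];
}
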