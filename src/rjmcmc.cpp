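#include <Rcpp.h>
#include "pruning.h"
using namespace Rcpp;

// Reversible-jump MCMC over rate-shift configurations for a continuous
// trait on a time-calibrated tree (trait-mode macroevolutionary-mixture
// model). A configuration is a set of shift events, each placed at an
// absolute time on an edge and opening a new regime with instantaneous
// rate beta(t) = beta * exp(b * (t - t0)) inherited by everything
// downstream until overridden. The likelihood is the contrasts REML value
// on the tree whose edge "lengths" are the accumulated variances
// integral beta(t) dt.
//
// Priors: k ~ Poisson(gamma); event locations uniform on the tree;
// log(beta) ~ Normal(beta_meanlog, beta_sdlog); b ~ Normal(0, b_sd)
// (b fixed at zero when time_varying = 0). Birth proposals draw location
// and regime parameters from the prior, so the Green acceptance factor
// reduces to (L'/L) * (gamma/(k+1)) * (p_death/p_birth).

struct Event {
  int edge;       // 0-based edge index
  double t;       // absolute time from the root
  double beta;    // regime initial rate (trait^2 / time)
  double b;       // rate-change exponent (1 / time)
};

struct Regime {
  double beta, b, t0;
};

static inline double regime_integral(const Regime& r, double a, double c) {
  // integral of beta * exp(b * (t - t0)) over [a, c]
  if (std::fabs(r.b) < 1e-10) return r.beta * (c - a);
  return (r.beta / r.b) *
         (std::exp(r.b * (c - r.t0)) - std::exp(r.b * (a - r.t0)));
}

class ShiftModel {
 public:
  int E, n_tip, maxnode;
  std::vector<int> par, chi, po, pre, paredge;  // paredge: -1 if from root
  std::vector<double> elen, tstart;
  std::vector<double> tipval;
  std::vector<double> cumlen;
  double Ltot;

  ShiftModel(IntegerMatrix edge, NumericVector edge_length,
             NumericVector t_start, IntegerVector postorder,
             IntegerVector preorder, IntegerVector parent_edge, int ntip,
             NumericVector tip_values)
      : E(edge.nrow()), n_tip(ntip) {
    par.resize(E); chi.resize(E); po.resize(E); pre.resize(E);
    paredge.resize(E); elen.resize(E); tstart.resize(E); cumlen.resize(E);
    maxnode = n_tip;
    double cl = 0.0;
    for (int e = 0; e < E; ++e) {
      par[e] = edge(e, 0);
      chi[e] = edge(e, 1);
      if (par[e] > maxnode) maxnode = par[e];
      if (chi[e] > maxnode) maxnode = chi[e];
      elen[e] = edge_length[e];
      tstart[e] = t_start[e];
      paredge[e] = parent_edge[e] - 1;  // R sends 0 for root children
      cl += elen[e];
      cumlen[e] = cl;
    }
    Ltot = cl;
    for (int i = 0; i < E; ++i) {
      po[i] = postorder[i] - 1;
      pre[i] = preorder[i] - 1;
    }
    tipval.assign(tip_values.begin(), tip_values.end());
  }

  // effective (variance) lengths under a configuration
  void effective_lengths(const std::vector<Event>& ev, const Regime& root,
                         std::vector<double>& evar,
                         std::vector<Regime>& regime_end) const {
    // bucket events by edge, sorted by time
    std::vector<std::vector<const Event*> > by_edge(E);
    for (std::size_t i = 0; i < ev.size(); ++i)
      by_edge[ev[i].edge].push_back(&ev[i]);
    for (int e = 0; e < E; ++e) {
      if (by_edge[e].size() > 1)
        std::sort(by_edge[e].begin(), by_edge[e].end(),
                  [](const Event* a, const Event* b) { return a->t < b->t; });
    }
    for (int i = 0; i < E; ++i) {
      int e = pre[i];
      Regime cur = (paredge[e] >= 0) ? regime_end[paredge[e]] : root;
      double a = tstart[e], end = tstart[e] + elen[e];
      double acc = 0.0;
      for (std::size_t j = 0; j < by_edge[e].size(); ++j) {
        const Event* s = by_edge[e][j];
        acc += regime_integral(cur, a, s->t);
        cur.beta = s->beta;
        cur.b = s->b;
        cur.t0 = s->t;
        a = s->t;
      }
      acc += regime_integral(cur, a, end);
      evar[e] = acc;
      regime_end[e] = cur;
    }
  }

  double loglik(const std::vector<Event>& ev, const Regime& root) const {
    std::vector<double> evar(E);
    std::vector<Regime> regime_end(E);
    effective_lengths(ev, root, evar, regime_end);
    for (int e = 0; e < E; ++e)
      if (!(evar[e] > 0.0) || !std::isfinite(evar[e])) return R_NegInf;
    return bm_reml_core(par, chi, evar, po, n_tip, maxnode, tipval.data(),
                        0.0);
  }

  // pick a point uniformly on the tree; returns edge, sets tpos
  int sample_point(double* tpos) const {
    double u = unif_rand() * Ltot;
    int lo = 0, hi = E - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cumlen[mid] < u) lo = mid + 1; else hi = mid;
    }
    double prev = (lo == 0) ? 0.0 : cumlen[lo - 1];
    *tpos = tstart[lo] + (u - prev);
    double end = tstart[lo] + elen[lo];
    if (*tpos >= end) *tpos = std::nextafter(end, tstart[lo]);
    return lo;
  }
};

static inline double dlnorm_log(double x, double ml, double sl) {
  double z = (std::log(x) - ml) / sl;
  return -std::log(x * sl) - 0.918938533204672742 - 0.5 * z * z;
}
static inline double dnorm_log(double x, double sd) {
  double z = x / sd;
  return -std::log(sd) - 0.918938533204672742 - 0.5 * z * z;
}

// [[Rcpp::export]]
List rjmcmc_run_cpp(IntegerMatrix edge, NumericVector edge_length,
                    NumericVector t_start, IntegerVector postorder,
                    IntegerVector preorder, IntegerVector parent_edge,
                    int n_tip, NumericVector tip_values, double ngen_d,
                    int thin, double gamma, double beta_meanlog,
                    double beta_sdlog, double b_sd, int time_varying,
                    int flat_likelihood, double beta_init, double move_scale_b,
                    double move_scale_beta) {
  ShiftModel M(edge, edge_length, t_start, postorder, preorder, parent_edge,
               n_tip, tip_values);
  RNGScope scope;

  std::vector<Event> ev;
  Regime root;
  root.beta = beta_init;
  root.b = 0.0;
  root.t0 = 0.0;

  double ll = flat_likelihood ? 0.0 : M.loglik(ev, root);
  long long ngen = (long long)ngen_d;

  // move probabilities
  double p_birth, p_death, p_move, p_scale, p_b;
  if (time_varying) {
    p_birth = 0.15; p_death = 0.15; p_move = 0.20; p_scale = 0.30; p_b = 0.20;
  } else {
    p_birth = 0.20; p_death = 0.20; p_move = 0.25; p_scale = 0.35; p_b = 0.0;
  }

  long long n_out = ngen / thin;
  std::vector<double> out_ll, out_lp, out_rootbeta, out_rootb;
  std::vector<int> out_k, out_gen;
  out_ll.reserve(n_out); out_lp.reserve(n_out); out_k.reserve(n_out);
  out_gen.reserve(n_out); out_rootbeta.reserve(n_out); out_rootb.reserve(n_out);
  std::vector<int> ev_sample, ev_edge;
  std::vector<double> ev_t, ev_beta, ev_b;

  double acc[5] = {0, 0, 0, 0, 0}, tried[5] = {0, 0, 0, 0, 0};

  double lgam = std::log(gamma);

  for (long long g = 1; g <= ngen; ++g) {
    double u = unif_rand();
    int k = (int)ev.size();
    if (u < p_birth) {
      // birth: location uniform on the tree, marks from the prior
      tried[0] += 1;
      Event ne;
      ne.edge = M.sample_point(&ne.t);
      ne.beta = std::exp(beta_meanlog + beta_sdlog * norm_rand());
      ne.b = time_varying ? b_sd * norm_rand() : 0.0;
      ev.push_back(ne);
      double ll2 = flat_likelihood ? 0.0 : M.loglik(ev, root);
      double logA = (ll2 - ll) + lgam - std::log((double)(k + 1)) +
                    std::log(p_death / p_birth);
      if (std::log(unif_rand()) < logA) {
        ll = ll2;
        acc[0] += 1;
      } else {
        ev.pop_back();
      }
    } else if (u < p_birth + p_death) {
      tried[1] += 1;
      if (k > 0) {
        int i = (int)std::floor(unif_rand() * k);
        if (i >= k) i = k - 1;
        Event saved = ev[i];
        ev[i] = ev[k - 1];
        ev.pop_back();
        double ll2 = flat_likelihood ? 0.0 : M.loglik(ev, root);
        double logA = (ll2 - ll) + std::log((double)k) - lgam +
                      std::log(p_birth / p_death);
        if (std::log(unif_rand()) < logA) {
          ll = ll2;
          acc[1] += 1;
        } else {
          ev.push_back(saved);
          std::swap(ev[i], ev[ev.size() - 1]);
        }
      }
    } else if (u < p_birth + p_death + p_move) {
      tried[2] += 1;
      if (k > 0) {
        int i = (int)std::floor(unif_rand() * k);
        if (i >= k) i = k - 1;
        Event saved = ev[i];
        if (unif_rand() < 0.5) {
          // relocate within the same edge (symmetric)
          double a = M.tstart[saved.edge];
          double end = a + M.elen[saved.edge];
          ev[i].t = a + unif_rand() * (end - a);
          if (ev[i].t >= end) ev[i].t = std::nextafter(end, a);
        } else {
          // global relocation, uniform on the tree (symmetric)
          ev[i].edge = M.sample_point(&ev[i].t);
        }
        double ll2 = flat_likelihood ? 0.0 : M.loglik(ev, root);
        if (std::log(unif_rand()) < (ll2 - ll)) {
          ll = ll2;
          acc[2] += 1;
        } else {
          ev[i] = saved;
        }
      }
    } else if (u < p_birth + p_death + p_move + p_scale) {
      // multiplier update of one regime's beta (root regime included)
      tried[3] += 1;
      int i = (int)std::floor(unif_rand() * (k + 1));
      if (i > k) i = k;
      double* target = (i == 0) ? &root.beta : &ev[i - 1].beta;
      double old = *target;
      double m = std::exp(move_scale_beta * (unif_rand() - 0.5));
      *target = old * m;
      double ll2 = flat_likelihood ? 0.0 : M.loglik(ev, root);
      double logA = (ll2 - ll) +
                    dlnorm_log(*target, beta_meanlog, beta_sdlog) -
                    dlnorm_log(old, beta_meanlog, beta_sdlog) + std::log(m);
      if (std::log(unif_rand()) < logA) {
        ll = ll2;
        acc[3] += 1;
      } else {
        *target = old;
      }
    } else {
      // random-walk update of one regime's b
      tried[4] += 1;
      int i = (int)std::floor(unif_rand() * (k + 1));
      if (i > k) i = k;
      double* target = (i == 0) ? &root.b : &ev[i - 1].b;
      double old = *target;
      *target = old + move_scale_b * norm_rand();
      double ll2 = flat_likelihood ? 0.0 : M.loglik(ev, root);
      double logA = (ll2 - ll) + dnorm_log(*target, b_sd) - dnorm_log(old, b_sd);
      if (std::log(unif_rand()) < logA) {
        ll = ll2;
        acc[4] += 1;
      } else {
        *target = old;
      }
    }

    if (g % thin == 0) {
      int kk = (int)ev.size();
      double lp = -gamma + kk * lgam - R::lgammafn(kk + 1.0) -
                  kk * std::log(M.Ltot) +
                  dlnorm_log(root.beta, beta_meanlog, beta_sdlog);
      if (time_varying) lp += dnorm_log(root.b, b_sd);
      for (int i = 0; i < kk; ++i) {
        lp += dlnorm_log(ev[i].beta, beta_meanlog, beta_sdlog);
        if (time_varying) lp += dnorm_log(ev[i].b, b_sd);
      }
      int sid = (int)(g / thin);
      out_gen.push_back(sid);
      out_ll.push_back(flat_likelihood ? 0.0 : ll);
      out_lp.push_back(lp);
      out_k.push_back(kk);
      out_rootbeta.push_back(root.beta);
      out_rootb.push_back(root.b);
      for (int i = 0; i < kk; ++i) {
        ev_sample.push_back(sid);
        ev_edge.push_back(ev[i].edge + 1);
        ev_t.push_back(ev[i].t);
        ev_beta.push_back(ev[i].beta);
        ev_b.push_back(ev[i].b);
      }
    }
    if (g % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc_rate(5);
  for (int i = 0; i < 5; ++i)
    acc_rate[i] = tried[i] > 0 ? acc[i] / tried[i] : NA_REAL;
  acc_rate.names() =
      CharacterVector::create("birth", "death", "move", "scale_beta",
                              "perturb_b");

  return List::create(
      _["sample"] = out_gen, _["loglik"] = out_ll, _["logprior"] = out_lp,
      _["nshifts"] = out_k, _["root_beta"] = out_rootbeta,
      _["root_b"] = out_rootb, _["ev_sample"] = ev_sample,
      _["ev_edge"] = ev_edge, _["ev_time"] = ev_t, _["ev_beta"] = ev_beta,
      _["ev_b"] = ev_b, _["acceptance"] = acc_rate,
      _["total_tree_length"] = M.Ltot);
}
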