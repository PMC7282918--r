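---
title: "Pulsed trait evolution and rate shifts on time-calibrated trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsed trait evolution and rate shifts on time-calibrated trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`levyshift` asks two questions about a continuous phenotype measured across
the tips of a time-calibrated phylogeny — in the motivating application, the
relative expression of a toxin family across venom transcriptomes of ~50
snake species on a tree with a ~60 My root:

1. **Mode**: does the trait evolve incrementally (Brownian motion, an
   Ornstein–Uhlenbeck pull towards an optimum, an early burst of change) or
   in rapid pulses (a Lévy process with jumps)?
2. **Tempo**: where on the tree, and when, did the *rate* of evolution
   shift, and how has the rate changed through time?

This vignette records the models, the numerics, and the design choices that
were genuinely open, plus what the synthetic-data tests do and do not
establish.

## The candidate models of trait evolution

All nine fitted models describe the increment of a trait X(t) along a
branch. With the root state profiled out (REML), the drift of a Lévy
process is not identifiable on an ultrametric tree, so all models are
driftless in fitting; the drift parameter exists in the simulator for
completeness.

* **BM**: Gaussian increments, variance $\sigma^2 t$ over time $t$.
* **OU**: pull $\alpha$ (1/My) towards an optimum; fitted by rescaling the
  tree so that BM on the rescaled tree reproduces the fixed-root OU
  covariance $\frac{\sigma^2}{2\alpha} e^{-2\alpha(T-s)}(1 - e^{-2\alpha s})$
  for tips whose MRCA sits at height $s$ on a tree of depth $T$. The
  optimum $\theta$ is not identifiable separately from the profiled root
  state and is not a counted parameter.
* **EB**: the instantaneous BM rate decays as $e^{rt}$, $r \le 0$; a branch
  spanning $[t_1, t_2]$ contributes variance $(e^{r t_2} - e^{r t_1})/r$.
* **JN** (jump normal): compound-Poisson jumps, count $\sim$
  Poisson($\lambda t$), sizes $\sim$ N(0, $\delta^2$) — stasis punctuated
  by rare pulses.
* **NIG**: symmetric centred normal-inverse-Gaussian increments with tail
  parameter $\alpha_{nig}$ and scale $\delta_{nig}$ — an infinitely active
  pure-jump process modelling constant small pulses. Characteristic
  exponent $\psi(k) = \delta_{nig}(\alpha_{nig} - \sqrt{\alpha_{nig}^2 + k^2})$.
* **BMJN, BMNIG**: jumps plus an independent Brownian component.
* **EBJN, EBNIG**: the jump process run on the EB-rescaled clock (both the
  diffusive and jump intensities decay together).

Every model carries a free Gaussian **tip noise** SD $\sigma_{tip}$,
standing in for intraspecific sampling plus measurement error: observed tip
values are Normal(true species mean, $\sigma_{tip}^2$).

Parameter counts (root state excluded): BM 2, OU 3, EB 3, JN 3, NIG 3,
BMJN 4, BMNIG 4, EBJN 4, EBNIG 4.

## REML likelihoods

For the Gaussian models the likelihood is computed exactly by phylogenetic
independent contrasts on the (rescaled) tree, with $\sigma_{tip}^2$ added
to each tip's terminal variance; polytomies are handled by merging a
node's children sequentially, which leaves the product of contrast
densities invariant. The contrast likelihood equals the full multivariate
normal likelihood with the grand mean profiled out, and is cross-checked
in the tests against a dense-covariance restricted-likelihood oracle to
1e-8.

For the pulsed models there is no closed form, so the package uses a
pruning recursion in which each node's conditional density lives on a
regular grid:

* each branch's increment density is obtained by inverting its
  characteristic function $\exp(t\,\psi(k))$ with an FFT;
* a tip observation enters through an exact spectral phase shift (no
  interpolation), with the tip-noise Gaussian folded into the same
  transform, so $\sigma_{tip} = 0$ is representable;
* the root state is integrated against a flat prior, which is exactly the
  REML construction — for Gaussian models the grid likelihood agrees with
  the contrasts value to about 1e-3 at the default grid.

**Numerical choices.** The default grid has 1024 points (any power of two
is accepted; `refine = TRUE` doubles until the log-likelihood moves less
than 1e-3, capped at 8192). The grid extent is the data range padded by
twice the data span on each side, enlarged automatically when a branch
increment density is wider than that (6 SD of the widest branch density);
a hard error reports any branch whose increment density still leaks more
than 1e-4 of its mass into the outer 5% of the grid. Signed intermediate
values are kept throughout — the small negative ringing of a spectral
representation must cancel, not be rectified, or the quadrature loses its
accuracy. One genuine limitation remains: a density narrower than the grid
spacing (e.g. a pure-jump model with $\sigma_{tip} \to 0$, whose branch
increments contain an atom at zero) is not representable on the grid, and
letting the optimiser descend into that regime produces spurious
likelihood. `fit_model()` therefore floors $\sigma_{tip}$ at 1.5 grid
spacings for pulsed models. The floor is a numerical resolution limit, not
a biological prior; the Gaussian models are computed exactly and need no
floor.

**Optimisation.** Bounded quasi-Newton (L-BFGS-B) on log-transformed
positive parameters ($r$ as $-e^u$), ten restarts by default — the first
start is data-driven (a contrasts-based BM rate estimate split across
components), the rest disperse it; non-converged fits are flagged and
refused by the comparison step unless overridden.

## Model comparison

Fits are compared by Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. Because the six jump
models rarely differ much in fit, they are *clubbed*: the pulsed class is
represented by the **maximum** weight among the jump models (not the sum),
while BM, OU and EB keep their own weights. A class is selected only if
its weight is at least twice every competitor's; otherwise the comparison
is reported as inconclusive. The two-fold rule is deliberately blunt; it
trades statistical elegance for an unambiguous call across many
simultaneous comparisons. AIC (not AICc) is the default to match the
weighted-AIC convention of comparable analyses.

## Rate-shift inference

The second analysis models the trait as Brownian motion whose
instantaneous rate $\beta(t)$ is piecewise defined by a configuration of
*shift events* on the tree. Each event sits at an absolute time on a
branch and opens a regime with rate
$\beta(t) = \beta_{init} e^{b (t - t_{shift})}$, inherited by everything
downstream until overridden by a nested shift. Integrating $\beta(t)$
along each branch reduces the model to plain BM on a tree of "effective"
branch lengths, evaluated by the same contrasts REML.

Configurations are sampled by reversible-jump MCMC:

* prior: shift count $\sim$ Poisson(`expected_shifts`, default 1 — a
  conservative null that favours zero shifts); locations uniform over the
  tree; $\log \beta_{init} \sim$ N(centred on the data's contrasts-based
  BM rate estimate, SD 2 natural-log units); $b \sim$ N(0, 0.05/My).
  The Poisson mean is a fixed hyperparameter rather than hyperprior-drawn,
  which keeps the prior mass on each shift count analytic — exactly what
  the Bayes factor needs.
* moves: add / delete a shift (marks proposed from the prior, so the
  Green acceptance factor is exactly $(L'/L)\,\gamma/(k{+}1)\,p_d/p_b$),
  relocate a shift (half local within its branch, half global), rescale a
  regime's $\beta_{init}$ (log-multiplier), perturb a regime's $b$.
  A `time_varying = FALSE` mode pins every $b$ at 0.
* validation: with the likelihood held flat the chain reproduces the
  Poisson prior on the shift count (chi-square goodness of fit in the test
  suite), which exercises the trans-dimensional bookkeeping end to end.

Downstream summaries follow the conventions of phenotypic
macroevolutionary-mixture analysis: a **Bayes factor** for $\ge 1$ shift
versus 0 computed from posterior versus analytic prior odds (reported as a
lower bound with one pseudo-count when no zero-shift sample remains); a
**95% credible set of distinct configurations** keyed by the set of
branches carrying *core* shifts — branches whose marginal shift
probability exceeds 5× its prior expectation (Poisson mean × branch
length / total tree length), so incidental prior-driven shifts do not
fragment the set; the **best (MAP) configuration** with posterior-mean
regime parameters; per-branch mean rates (the numbers behind a phylorate
plot, exported as TSV and comment-annotated Newick); and
**rate-through-time** curves — at each time point the mean rate across
lineages alive then, averaged over the posterior with a central 90% band,
with times before a clade's origin reported as absent rather than zero.

Chains are bit-reproducible given a seed. Convergence is judged the
conventional way: effective sample size (Geyer initial-positive-sequence
estimator, capped at the series length) of the log-likelihood and
shift-count series above 200, plus trace plots via `autoplot()`.

## Data handling

Expression tables are species × toxin relative abundances; repeated
species rows are replicate transcriptomes. Choices a user should know:

* A missing cell is recorded as abundance 0: in a relative composition an
  undetected toxin is absent, not unknown.
* The presence filter keeps toxins detected (abundance > 0 in any
  replicate) in at least a fraction (default 50%) of *species*.
* Scaling: per-toxin species means divided by the square root of the
  average within-species variance (sample variance, n−1, over species
  with ≥ 2 replicates) — i.e. standardisation to within-species SD units.
  Dividing by the variance itself is one flag away
  (`divisor = "variance"`), and the constant is stored on the result. If
  no species has replicates the constant falls back to 1 with a warning.
* No transform is applied by default; `log` and `logit` are exposed as
  options since relative abundances are compositional.
* Tree–data alignment is by exact label match, with pruning that
  collapses degree-2 nodes and preserves root-to-tip depth.

## The synthetic-data generator

Every stage is testable without downloads. `simulate_pure_birth_tree()`
draws Yule trees rescaled to a fixed depth; `simulate_levy_traits()`
simulates all nine models exactly (OU via its Gaussian transition, NIG via
its inverse-Gaussian mixture representation, EB variants via the rescaled
clock); `simulate_shifted_bm()` simulates rate-shifted BM from a painted
configuration. All draws flow from a single seed in the tree's stored
edge order, so a fixed seed reproduces every branch's increments
regardless of traversal implementation.

`make_demo_data()` emulates the shape of a real comparative venom dataset:
52 species in three clades (stand-ins for the three venomous snake
families, with clade-specific composition offsets), 60 My depth, 10 toxin
families with a stated generating model each — mostly pulsed, one
rate-shifted BM toxin with a known shift on a family stem branch, one
sparse toxin for the presence filter — replicate transcriptomes for ten
species, and rows normalised to sum to one. The mapping from simulated
trait to relative abundance (exponentiate, normalise) is a convenience
for producing a well-formed composition; it mildly distorts the
generating model, which is why quantitative model-recovery tests run on
the traits directly and the demo serves as an end-to-end smoke test.

What passing tests on these data show: the likelihoods are correct
(against closed forms, dense-matrix and Monte-Carlo oracles), parameters
and model classes are recoverable at realistic sizes (50–100 tips), the
sampler targets its stated posterior, and strong shifts are detected and
localised. What they cannot show: that real venom-expression data satisfy
the models (compositional constraints, non-Gaussian measurement error and
taxon sampling biases are not emulated), nor that the presence filter or
scaling are optimal for any particular dataset.

## Problem sizes used in the shipped checks

The test suite runs desk-scale versions of every claim: 10-tip oracle
comparisons; a 3-tip Monte-Carlo likelihood oracle with 2×10⁶ draws;
50 replicates of BM rate recovery and 25 + 25 replicates of
pulsed-versus-BM class recovery at 100 tips (single-start fits on a
512-point grid); prior recovery and ESS on 2×10⁶-generation chains
(thinning 200) at 50 tips; and 20 shift-detection replicates at
4×10⁵ generations. The sampler's production settings
(10⁹ generations, write frequency 10⁵) are configuration-reachable but
deliberately not exercised in tests.

## Known limitations

* Single-optimum OU only; no multi-regime OU.
* The rate-shift model is BM-based; no pulsed likelihood inside the
  rjMCMC.
* The pulsed-model grid likelihood needs $\sigma_{tip}$ (or a Brownian
  component) large enough to resolve on the grid — see the numerical
  floor above.
* Bayes factors are reported raw; no support threshold is imposed.
* Exact label matching only; taxonomy reconciliation is the user's
  responsibility (a synonym map can be applied upstream).
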