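#' REML log-likelihood of rate-shifted Brownian motion
#'
#' Contrasts REML likelihood of the tree whose per-branch variance
#' accumulations follow a [shift_configuration()]
#' (see [effective_branch_lengths()]). A zero-shift configuration with
#' `root_b = 0` reduces exactly to constant-rate BM with
#' `sigma2 = root_beta`.
#'
#' @param tree Time tree.
#' @param trait Trait values for all tips.
#' @param config A [shift_configuration()].
#' @return The REML log-likelihood.
#' @export
shifted_bm_loglik <- function(tree, trait, config) {
  x <- match_trait_to_tree(tree, trait)
  if (length(x) < 3) stop("need at least 3 tips", call. = FALSE)
  evar <- effective_branch_lengths(tree, config)
  if (any(evar <= 0)) stop("non-positive accumulated variance on some ",
                           "branch", call. = FALSE)
  arr <- tree_arrays(tree)
  bm_reml_loglik_vars_cpp(arr$edge, evar, arr$postorder, arr$n_tip,
                          unname(x))
}

#' Reversible-jump MCMC over rate-shift configurations
#'
#' Samples shift configurations for a continuous trait on a time-calibrated
#' tree from the posterior with: a Poisson prior with mean
#' `expected_shifts` on the number of shifts, uniform shift locations over
#' the tree, a broad log-normal prior on each regime's initial rate
#' (`sdlog = 2`; `meanlog` defaults to the log of the contrasts-based BM
#' rate estimate of the data) and a Normal(0, `b_prior_sd`) prior on the
#' rate-change exponent. The move set is add-shift / delete-shift (a
#' reversible pair with prior-drawn marks, so the Green acceptance factor is
#' exact), relocate shift, rescale a regime's rate, and perturb a regime's
#' exponent; the likelihood is [shifted_bm_loglik()]. Fixed seed and
#' settings give a bit-reproducible chain.
#'
#' @param tree Time tree.
#' @param trait Trait values for all tips.
#' @param ngenerations Number of MCMC generations.
#' @param thin Write (thinning) interval in generations.
#' @param expected_shifts Poisson prior mean on the shift count.
#' @param seed Optional integer seed.
#' @param time_varying If `TRUE` (default) regimes carry an exponentially
#'   time-varying rate (free `b`); if `FALSE`, `b` is fixed at 0.
#' @param flat_likelihood If `TRUE` the likelihood is held constant so the
#'   chain samples the prior (used for sampler validation).
#' @param beta_meanlog,beta_sdlog Log-normal prior on regime initial rates.
#' @param b_prior_sd SD of the Normal prior on `b` (1/time units).
#' @param move_scale_beta,move_scale_b Proposal scales.
#' @return A `rateshift_sample` object: `samples` tibble (one row per
#'   thinned sample: `sample`, `loglik`, `logprior`, `nshifts`,
#'   `root_beta`, `root_b`), `events` tibble (one row per shift per
#'   sample), acceptance-rate diagnostics, the settings, and the tree.
#' @export
rjmcmc_run <- function(tree, trait, ngenerations = 2e6, thin = 200,
                       expected_shifts = 1, seed = NULL,
                       time_varying = TRUE, flat_likelihood = FALSE,
                       beta_meanlog = NULL, beta_sdlog = 2,
                       b_prior_sd = 0.05, move_scale_beta = 1.4,
                       move_scale_b = 0.02) {
  x <- match_trait_to_tree(tree, trait)
  if (length(x) < 3) stop("need at least 3 tips", call. = FALSE)
  stopifnot(ngenerations >= thin, thin >= 1, expected_shifts > 0)
  if (is.null(beta_meanlog)) {
    beta_meanlog <- log(max(bm_sigma2_hat(tree, x), 1e-12))
  }
  arr <- tree_arrays(tree)
  res <- with_seed(seed, {
    rjmcmc_run_cpp(arr$edge, arr$edge_length, arr$t_start, arr$postorder,
                   arr$preorder, arr$parent_edge, arr$n_tip, unname(x),
                   as.numeric(ngenerations), as.integer(thin),
                   expected_shifts, beta_meanlog, beta_sdlog, b_prior_sd,
                   as.integer(time_varying), as.integer(flat_likelihood),
                   exp(beta_meanlog), move_scale_b, move_scale_beta)
  })
  samples <- tibble::tibble(sample = res$sample, loglik = res$loglik,
                            logprior = res$logprior, nshifts = res$nshifts,
                            root_beta = res$root_beta, root_b = res$root_b)
  events <- tibble::tibble(sample = res$ev_sample, edge = res$ev_edge,
                           time = res$ev_time, beta = res$ev_beta,
                           b = res$ev_b)
  acc <- tibble::tibble(move = names(res$acceptance),
                        acceptance = as.numeric(res$acceptance))
  acc$flag <- !is.na(acc$acceptance) &
    (acc$acceptance < 0.05 | acc$acceptance > 0.7)
  structure(list(samples = samples, events = events, acceptance = acc,
                 settings = list(ngenerations = ngenerations, thin = thin,
                                 expected_shifts = expected_shifts,
                                 seed = seed, time_varying = time_varying,
                                 flat_likelihood = flat_likelihood,
                                 beta_meanlog = beta_meanlog,
                                 beta_sdlog = beta_sdlog,
                                 b_prior_sd = b_prior_sd,
                                 total_tree_length = res$total_tree_length),
                 tree = tree),
            class = "rateshift_sample")
}

#' @export
print.rateshift_sample <- function(x, ...) {
  s <- x$settings
  cat("<rateshift_sample> ", nrow(x$samples), " thinned samples (",
      format(s$ngenerations, big.mark = ","), " generations, thin ",
      s$thin, ")\n", sep = "")
  cat("  expected shifts (Poisson prior mean): ", s$expected_shifts, "\n",
      sep = "")
  cat("  posterior shift-count distribution:\n")
  print(table(x$samples$nshifts))
  invisible(x)
}

# per-sample configuration key: the sorted set of (core) edges carrying
# shifts, "{}" when none
config_keys <- function(ids, ev) {
  by_sample <- split(ev$edge, factor(ev$sample, levels = ids))
  vapply(by_sample, function(e) {
    e <- sort(unique(e))
    if (length(e) == 0) "{}" else paste(e, collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

# drop the first `burnin` fraction of thinned samples
retain_samples <- function(sample, burnin) {
  stopifnot(burnin >= 0, burnin < 1)
  ids <- sample$samples$sample
  cut <- stats::quantile(ids, burnin, type = 1)
  keep <- ids > cut | burnin == 0
  list(samples = sample$samples[keep, , drop = FALSE],
       events = sample$events[sample$events$sample %in%
                                sample$samples$sample[keep], , drop = FALSE])
}

#' Bayes factor for at least one rate shift
#'
#' Posterior-to-prior odds of >= 1 shift versus 0 shifts, with the
#' analytically known Poisson prior. When no zero-shift sample was
#' observed, the posterior zero probability is replaced by one pseudo-count
#' (1 / sample size) and the Bayes factor reported as a lower bound.
#'
#' @param sample A `rateshift_sample`.
#' @param burnin Fraction of initial samples to discard (default 0.1).
#' @return A `bayes_factor_result` list: `bf`, `is_bound`, posterior and
#'   prior shift-count probabilities.
#' @export
compute_bayes_factor <- function(sample, burnin = 0.1) {
  stopifnot(inherits(sample, "rateshift_sample"))
  kept <- retain_samples(sample, burnin)
  k <- kept$samples$nshifts
  S <- length(k)
  gamma <- sample$settings$expected_shifts
  p0_prior <- stats::dpois(0, gamma)
  p0_post <- mean(k == 0)
  is_bound <- FALSE
  if (p0_post == 0) {
    p0_post <- 1 / S
    is_bound <- TRUE
  }
  bf <- ((1 - p0_post) / p0_post) / ((1 - p0_prior) / p0_prior)
  structure(list(bf = bf, is_bound = is_bound,
                 posterior = tibble::tibble(k = as.integer(names(table(k))),
                                            prob = as.numeric(table(k)) / S),
                 prior_p0 = p0_prior, posterior_p0 = mean(k == 0),
                 n_samples = S),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat("<bayes_factor_result> BF(>=1 shift vs 0) ",
      if (x$is_bound) "> " else "= ", format(x$bf, digits = 4), "\n",
      sep = "")
  invisible(x)
}

# marginal posterior probability of >= 1 shift per edge, with the
# prior-relative core-shift threshold
core_shift_edges <- function(sample, burnin = 0.1, core_factor = 5) {
  kept <- retain_samples(sample, burnin)
  S <- nrow(kept$samples)
  tree <- sample$tree
  E <- nrow(tree$edge)
  hit <- table(factor(unique(kept$events[c("sample", "edge")])$edge,
                      levels = seq_len(E)))
  marg <- as.numeric(hit) / S
  prior_expect <- sample$settings$expected_shifts * tree$edge.length /
    sample$settings$total_tree_length
  tibble::tibble(edge = seq_len(E), marginal_prob = marg,
                 prior_expectation = prior_expect,
                 core = marg >= core_factor * prior_expect & marg > 0)
}

#' Credible set of distinct shift configurations
#'
#' Distinct configurations are keyed by the set of branches carrying *core*
#' shifts — shifts whose marginal branch probability exceeds `core_factor`
#' times its prior expectation (prior expectation = Poisson mean x branch
#' length / total tree length); incidental shifts on other branches do not
#' split configurations. Configurations are ranked by posterior frequency
#' and the smallest prefix reaching `cumulative` probability is returned.
#'
#' @param sample A `rateshift_sample`.
#' @param cumulative Target cumulative posterior probability (default 0.95).
#' @param core_factor Prior-relative threshold for core shifts (default 5).
#' @param burnin Fraction of initial samples to discard.
#' @return A tibble (class `credible_shift_set`) with one row per distinct
#'   configuration: `rank`, `config` (key string), `edges` (list column),
#'   `frequency`, `cumulative`; the per-edge marginals are attached as
#'   attribute `"marginals"`.
#' @export
credible_shift_set <- function(sample, cumulative = 0.95, core_factor = 5,
                               burnin = 0.1) {
  stopifnot(inherits(sample, "rateshift_sample"))
  marg <- core_shift_edges(sample, burnin = burnin,
                           core_factor = core_factor)
  core <- marg$edge[marg$core]
  kept <- retain_samples(sample, burnin)
  ids <- kept$samples$sample
  ev <- kept$events[kept$events$edge %in% core, , drop = FALSE]
  key_by_sample <- config_keys(ids, ev)
  tab <- sort(table(key_by_sample), decreasing = TRUE)
  freq <- as.numeric(tab) / length(ids)
  cum <- cumsum(freq)
  n_keep <- which(cum >= cumulative)[1]
  if (is.na(n_keep)) n_keep <- length(freq)
  out <- tibble::tibble(
    rank = seq_len(n_keep),
    config = names(tab)[seq_len(n_keep)],
    edges = lapply(names(tab)[seq_len(n_keep)], function(s) {
      if (s == "{}") integer(0) else
        as.integer(strsplit(s, "+", fixed = TRUE)[[1]])
    }),
    frequency = freq[seq_len(n_keep)],
    cumulative = cum[seq_len(n_keep)])
  attr(out, "marginals") <- marg
  attr(out, "burnin") <- burnin
  class(out) <- c("credible_shift_set", class(out))
  out
}

#' Maximum a posteriori distinct shift configuration
#'
#' The highest-frequency configuration key from [credible_shift_set()],
#' with regime parameters set to posterior means over the samples matching
#' that key (per core branch: mean shift time, rate and exponent; root
#' regime likewise).
#'
#' @inheritParams credible_shift_set
#' @return A [shift_configuration()].
#' @export
best_shift_configuration <- function(sample, core_factor = 5,
                                     burnin = 0.1) {
  css <- credible_shift_set(sample, cumulative = 1, core_factor = core_factor,
                            burnin = burnin)
  best_edges <- css$edges[[1]]
  kept <- retain_samples(sample, burnin)
  ids <- kept$samples$sample
  ev <- kept$events
  core <- attr(css, "marginals")$edge[attr(css, "marginals")$core]
  key_by_sample <- config_keys(ids, ev[ev$edge %in% core, , drop = FALSE])
  match_ids <- ids[key_by_sample == css$config[1]]
  ms <- kept$samples[kept$samples$sample %in% match_ids, , drop = FALSE]
  if (length(best_edges) == 0) {
    return(shift_configuration(NULL, root_beta = mean(ms$root_beta),
                               root_b = mean(ms$root_b)))
  }
  evm <- ev[ev$sample %in% match_ids & ev$edge %in% best_edges, ,
            drop = FALSE]
  agg <- dplyr::summarise(dplyr::group_by(evm, .data$edge),
                          time = mean(.data$time),
                          beta = mean(.data$beta),
                          b = mean(.data$b), .groups = "drop")
  shift_configuration(agg, root_beta = mean(ms$root_beta),
                      root_b = mean(ms$root_b))
}
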