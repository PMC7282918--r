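test_that("effective branch lengths integrate the regime rate", {
  tr <- tree_from_text("(A:3,B:3);")
  # constant rate 2 on a branch of length 3
  cfg <- shift_configuration(NULL, root_beta = 2)
  expect_equal(effective_branch_lengths(tr, cfg), c(6, 6))

  # decaying regime: integral of e^(-t) over [0, 1]
  tr1 <- tree_from_text("(A:1,B:1);")
  cfg2 <- shift_configuration(NULL, root_beta = 1, root_b = -1)
  expect_equal(effective_branch_lengths(tr1, cfg2),
               rep(1 - exp(-1), 2), tolerance = 1e-12)

  # b -> 0 limit agrees with the constant-rate formula
  cfg3 <- shift_configuration(NULL, root_beta = 1, root_b = 1e-12)
  expect_equal(effective_branch_lengths(tr1, cfg3), c(1, 1),
               tolerance = 1e-9)

  # a mid-branch shift splits the integral
  cfg4 <- shift_configuration(
    data.frame(edge = 1, time = 1, beta = 5, b = 0), root_beta = 1)
  expect_equal(effective_branch_lengths(tr, cfg4)[1], 1 * 1 + 2 * 5)
  expect_equal(effective_branch_lengths(tr, cfg4)[2], 3)
})

test_that("shifts inherit downstream until overridden", {
  tr <- balanced3()  # ((A:1,B:1):1,C:2)
  stem <- which(tr$edge[, 2] == ape::getMRCA(tr, c("A", "B")))
  cfg <- shift_configuration(
    data.frame(edge = stem, time = 0.5, beta = 4, b = 0), root_beta = 1)
  ev <- effective_branch_lengths(tr, cfg)
  edge_A <- which(tr$edge[, 2] == which(tr$tip.label == "A"))
  edge_C <- which(tr$edge[, 2] == which(tr$tip.label == "C"))
  expect_equal(ev[stem], 0.5 * 1 + 0.5 * 4)
  expect_equal(ev[edge_A], 4)   # inherited regime
  expect_equal(ev[edge_C], 2)   # root regime untouched
})

test_that("zero-shift likelihood equals constant-rate BM exactly", {
  tr <- simulate_pure_birth_tree(15, 60, seed = 51)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 0.7),
                            seed = 52)
  cfg <- shift_configuration(NULL, root_beta = 0.7)
  expect_equal(shifted_bm_loglik(tr, x, cfg),
               reml_gaussian_loglik(tr, x, levy_model_spec("BM",
                                                           sigma2 = 0.7)),
               tolerance = 1e-9)
})

test_that("a true shift raises the likelihood over the no-shift fit", {
  gains <- vapply(1:20, function(i) {
    tr <- simulate_pure_birth_tree(30, 60, seed = 60 + i)
    nt <- ape::Ntip(tr)
    sizes <- vapply(seq_len(nrow(tr$edge)), function(e) {
      ch <- tr$edge[e, 2]
      if (ch <= nt) 1L else ape::Ntip(ape::extract.clade(tr, ch))
    }, integer(1))
    e <- which(sizes >= 8)[1]
    h <- ape::node.depth.edgelength(tr)
    cfg <- shift_configuration(
      data.frame(edge = e, time = h[tr$edge[e, 1]] +
                   0.5 * tr$edge.length[e], beta = 2, b = 0),
      root_beta = 1)
    x <- simulate_shifted_bm(tr, cfg, seed = 600 + i)
    # profile the overall rate scale on both sides so the comparison is
    # shape versus shape, not shape versus fitted rate
    prof <- function(config) {
      optimize(function(lc) {
        c2 <- config
        c2$root_beta <- config$root_beta * exp(lc)
        if (nrow(c2$events) > 0) c2$events$beta <- config$events$beta *
            exp(lc)
        -shifted_bm_loglik(tr, x, c2)
      }, c(-3, 3))$objective * -1
    }
    prof(cfg) - prof(shift_configuration(NULL, root_beta = 1))
  }, numeric(1))
  # the typical replicate favours the true painting
  expect_gt(median(gains), 0)
})

test_that("rescaling rates by c and contrasts by sqrt(c) is consistent", {
  tr <- simulate_pure_birth_tree(12, 60, seed = 53)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1),
                            seed = 54)
  cfg1 <- shift_configuration(NULL, root_beta = 1)
  x2 <- x
  x2$value <- x$value * sqrt(3)
  cfg3 <- shift_configuration(NULL, root_beta = 3)
  n1 <- nrow(x) - 1
  # Gaussian location-scale identity: ll(c*beta; sqrt(c)*x) =
  # ll(beta; x) - (n-1)/2 log(c)
  expect_equal(shifted_bm_loglik(tr, x2, cfg3),
               shifted_bm_loglik(tr, x, cfg1) - n1 / 2 * log(3),
               tolerance = 1e-6)
})

test_that("the chain is bit-reproducible for a fixed seed", {
  tr <- simulate_pure_birth_tree(10, 60, seed = 55)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1), seed = 56)
  m1 <- rjmcmc_run(tr, x, ngenerations = 2e4, thin = 20, seed = 77)
  m2 <- rjmcmc_run(tr, x, ngenerations = 2e4, thin = 20, seed = 77)
  expect_identical(m1$samples, m2$samples)
  expect_identical(m1$events, m2$events)
  m3 <- rjmcmc_run(tr, x, ngenerations = 2e4, thin = 20, seed = 78)
  expect_false(identical(m1$samples, m3$samples))
})

fake_sample <- function(k_values, events = NULL, tree = NULL,
                        expected_shifts = 1) {
  if (is.null(tree)) tree <- simulate_pure_birth_tree(10, 60, seed = 1)
  samples <- tibble::tibble(sample = seq_along(k_values), loglik = 0,
                            logprior = 0, nshifts = k_values,
                            root_beta = 1, root_b = 0)
  if (is.null(events)) {
    events <- tibble::tibble(sample = integer(), edge = integer(),
                             time = numeric(), beta = numeric(),
                             b = numeric())
  }
  structure(list(samples = samples, events = events,
                 acceptance = tibble::tibble(),
                 settings = list(ngenerations = length(k_values),
                                 thin = 1,
                                 expected_shifts = expected_shifts,
                                 total_tree_length = sum(tree$edge.length)),
                 tree = tree), class = "rateshift_sample")
}

test_that("Bayes factors follow the posterior-to-prior odds arithmetic", {
  # 500 zero-shift and 500 shifted samples under a Poisson(1) prior
  s <- fake_sample(rep(c(0L, 1L), each = 500))
  bf <- compute_bayes_factor(s, burnin = 0)
  expect_equal(bf$bf, 1 / (exp(1) - 1), tolerance = 1e-12)
  expect_false(bf$is_bound)

  # posterior identical to the prior: gamma = log(2) puts half the prior
  # mass on zero shifts, so 500/500 gives BF = 1 exactly
  s2 <- fake_sample(rep(c(0L, 1L), each = 500), expected_shifts = log(2))
  expect_equal(compute_bayes_factor(s2, burnin = 0)$bf, 1)

  # no zero-shift samples: reported as a pseudo-count bound
  s3 <- fake_sample(rep(1L, 1000))
  bf3 <- compute_bayes_factor(s3, burnin = 0)
  expect_true(bf3$is_bound)
  expect_equal(bf3$bf, (1 - 1e-3) / 1e-3 / (expm1(1)), tolerance = 1e-9)
})

test_that("credible shift sets key configurations by core branches", {
  tree <- simulate_pure_birth_tree(10, 60, seed = 2)
  # all zero-shift samples: the empty configuration with frequency 1
  s <- fake_sample(rep(0L, 200), tree = tree)
  css <- credible_shift_set(s, burnin = 0)
  expect_equal(nrow(css), 1)
  expect_equal(css$config, "{}")
  expect_equal(css$frequency, 1)

  # 60/40 split between one-shift (edge 3) and zero-shift samples
  ev <- tibble::tibble(sample = 1:120, edge = 3L, time = 30, beta = 2,
                       b = 0)
  s2 <- fake_sample(c(rep(1L, 120), rep(0L, 80)), events = ev, tree = tree)
  css2 <- credible_shift_set(s2, cumulative = 0.95, burnin = 0)
  expect_equal(nrow(css2), 2)
  expect_equal(css2$frequency, c(0.6, 0.4))

  # shifts scattered uniformly: no edge reaches the core threshold, so all
  # samples collapse into the empty-keyed class
  set.seed(3)
  E <- nrow(tree$edge)
  ev3 <- tibble::tibble(sample = 1:200,
                        edge = sample(E, 200, TRUE,
                                      prob = tree$edge.length),
                        time = 30, beta = 2, b = 0)
  ev3$time <- ape::node.depth.edgelength(tree)[tree$edge[ev3$edge, 1]] +
    0.5 * tree$edge.length[ev3$edge]
  s3 <- fake_sample(rep(1L, 200), events = ev3, tree = tree)
  css3 <- credible_shift_set(s3, burnin = 0)
  expect_equal(css3$config[1], "{}")
  expect_equal(css3$frequency[1], 1)
})

test_that("the best configuration is the top key with posterior-mean rates", {
  tree <- simulate_pure_birth_tree(10, 60, seed = 4)
  # use a short edge so its marginal probability clears the prior-relative
  # core threshold
  e <- which.min(tree$edge.length)
  ev <- tibble::tibble(sample = 1:120, edge = e,
                       time = seq(28, 32, length.out = 120),
                       beta = seq(1.5, 2.5, length.out = 120), b = 0)
  s <- fake_sample(c(rep(1L, 120), rep(0L, 80)), events = ev, tree = tree)
  best <- best_shift_configuration(s, burnin = 0)
  expect_equal(nrow(best$events), 1)
  expect_equal(best$events$edge, e)
  expect_equal(best$events$beta, 2, tolerance = 1e-9)
  expect_equal(best$events$time, 30, tolerance = 1e-9)

  s2 <- fake_sample(rep(0L, 100), tree = tree)
  best2 <- best_shift_configuration(s2, burnin = 0)
  expect_equal(nrow(best2$events), 0)
})

test_that("rate through time reflects the regime structure", {
  tree <- simulate_pure_birth_tree(10, 60, seed = 5)
  # constant-rate posterior: flat curve, zero-width band
  s <- fake_sample(rep(0L, 50), tree = tree)
  rtt <- rate_through_time(s, grid = 20, burnin = 0)
  expect_true(all(abs(rtt$rate_mean - 1) < 1e-9))
  expect_true(all(rtt$rate_upper - rtt$rate_lower < 1e-9))
  expect_true(all(rtt$rate_lower <= rtt$rate_mean + 1e-12 &
                    rtt$rate_mean <= rtt$rate_upper + 1e-12))

  # single decaying regime: strictly decreasing mean curve in absolute time
  s2 <- fake_sample(rep(0L, 50), tree = tree)
  s2$samples$root_b <- -0.05
  rtt2 <- rate_through_time(s2, grid = 20, burnin = 0)
  ordered <- rtt2$rate_mean[order(rtt2$time_before_present,
                                  decreasing = TRUE)]
  expect_true(all(diff(ordered) < 0))
})

test_that("clade-restricted curves are absent before the clade origin", {
  tree <- tree_from_text("((A:20,B:20):40,(C:50,D:50):10);")
  s <- fake_sample(rep(0L, 30), tree = tree)
  rtt <- rate_through_time(s, clade = c("A", "B"), grid = 30, burnin = 0)
  old <- rtt$time_before_present > 20 + 1e-6
  expect_true(all(is.na(rtt$rate_mean[old])))
  expect_true(all(!is.na(rtt$rate_mean[!old])))
})

test_that("clade rate ratios carry through to rate-through-time curves", {
  tree <- tree_from_text("((A:20,B:20):40,(C:20,D:20):40);")
  fast <- which(tree$edge[, 2] == ape::getMRCA(tree, c("A", "B")))
  ev <- tibble::tibble(sample = 1:40, edge = fast, time = 1, beta = 10,
                       b = 0)
  s <- fake_sample(rep(1L, 40), events = ev, tree = tree)
  r_fast <- rate_through_time(s, clade = c("A", "B"), grid = 10,
                              burnin = 0)
  r_slow <- rate_through_time(s, clade = c("C", "D"), grid = 10,
                              burnin = 0)
  recent <- r_fast$time_before_present < 15
  expect_equal(r_fast$rate_mean[recent] / r_slow$rate_mean[recent],
               rep(10, sum(recent)), tolerance = 1e-6)
})

test_that("branch rates average the per-sample effective rates", {
  tree <- balanced3()
  s <- fake_sample(rep(0L, 20), tree = tree)
  br <- branch_rates(s, burnin = 0)
  expect_equal(br$mean_rate, rep(1, nrow(tree$edge)))
  nwk <- annotated_newick(tree, br)
  expect_match(nwk, "\\[&rate=1\\]")
  expect_equal(length(gregexpr("&rate=", nwk)[[1]]), nrow(tree$edge))
})
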