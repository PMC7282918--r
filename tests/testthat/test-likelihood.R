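test_that("the single-contrast REML value matches its closed form", {
  tr <- tree_from_text("(A:1,B:1);")
  sp <- levy_model_spec("BM", sigma2 = 1, sigma_tip = 0)
  ll <- reml_gaussian_loglik(tr, trait_of(A = 0, B = 2), sp)
  # contrast -2 with variance 2: N(-2; 0, 2) density
  expect_equal(ll, -0.5 * log(4 * pi) - 1, tolerance = 1e-12)
})

test_that("tip noise is equivalent to lengthening pendant branches", {
  tr <- simulate_pure_birth_tree(8, 10, seed = 21)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1),
                            seed = 22)
  s2 <- 0.7
  c2 <- 0.3
  ll1 <- reml_gaussian_loglik(tr, x, levy_model_spec("BM", sigma2 = s2,
                                                     sigma_tip = sqrt(c2)))
  tr2 <- tr
  tips <- tr2$edge[, 2] <= ape::Ntip(tr2)
  tr2$edge.length[tips] <- tr2$edge.length[tips] + c2 / s2
  ll2 <- reml_gaussian_loglik(tr2, x, levy_model_spec("BM", sigma2 = s2,
                                                      sigma_tip = 0))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("contrasts REML equals the dense-covariance restricted likelihood", {
  tr <- simulate_pure_birth_tree(10, 60, seed = 23)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1,
                                                sigma_tip = 0.1), seed = 24)
  for (sp in list(levy_model_spec("BM", sigma2 = 0.8, sigma_tip = 0.2),
                  levy_model_spec("OU", sigma2 = 0.8, alpha = 0.05,
                                  sigma_tip = 0.2),
                  levy_model_spec("EB", sigma2 = 0.8, r = -0.03,
                                  sigma_tip = 0.2))) {
    expect_equal(reml_gaussian_loglik(tr, x, sp),
                 levyshift:::reml_gaussian_loglik_dense(tr, x, sp),
                 tolerance = 1e-10)
  }
})

test_that("contrasts REML handles polytomies (checked against dense oracle)", {
  tr <- tree_from_text("((A:1,B:1,C:1):1,(D:1.5,E:1.5):0.5);")
  x <- trait_of(A = 0.3, B = -0.2, C = 0.5, D = 1.2, E = 0.9)
  sp <- levy_model_spec("BM", sigma2 = 0.5, sigma_tip = 0.1)
  expect_equal(reml_gaussian_loglik(tr, x, sp),
               levyshift:::reml_gaussian_loglik_dense(tr, x, sp),
               tolerance = 1e-10)
})

test_that("grid likelihood agrees with Gaussian REML on Gaussian models", {
  tr <- simulate_pure_birth_tree(10, 60, seed = 25)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1,
                                                sigma_tip = 0.1), seed = 26)
  for (sp in list(levy_model_spec("BM", sigma2 = 0.9, sigma_tip = 0.2),
                  levy_model_spec("OU", sigma2 = 0.9, alpha = 0.02,
                                  sigma_tip = 0.2),
                  levy_model_spec("EB", sigma2 = 0.9, r = -0.02,
                                  sigma_tip = 0.2))) {
    expect_equal(levy_reml_loglik(tr, x, sp),
                 reml_gaussian_loglik(tr, x, sp), tolerance = 1e-3)
  }
})

test_that("BMJN collapses to BM when the jump intensity is zero", {
  tr <- simulate_pure_birth_tree(12, 60, seed = 27)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 0.5,
                                                sigma_tip = 0.2), seed = 28)
  bmjn <- levy_model_spec("BMJN", sigma2 = 0.5, lambda = 0, delta = 1,
                          sigma_tip = 0.3)
  bm <- levy_model_spec("BM", sigma2 = 0.5, sigma_tip = 0.3)
  expect_equal(levy_reml_loglik(tr, x, bmjn),
               reml_gaussian_loglik(tr, x, bm), tolerance = 1e-4)
})

test_that("likelihoods are invariant to adding a constant to the trait", {
  tr <- simulate_pure_birth_tree(10, 60, seed = 29)
  x <- simulate_levy_traits(tr, levy_model_spec("JN", lambda = 0.1,
                                                delta = 2, sigma_tip = 0.2),
                            seed = 30)
  x2 <- x
  x2$value <- x2$value + 7.3
  spg <- levy_model_spec("BM", sigma2 = 0.5, sigma_tip = 0.2)
  expect_equal(reml_gaussian_loglik(tr, x, spg),
               reml_gaussian_loglik(tr, x2, spg), tolerance = 1e-6)
  spj <- levy_model_spec("JN", lambda = 0.1, delta = 2, sigma_tip = 0.3)
  expect_equal(levy_reml_loglik(tr, x, spj),
               levy_reml_loglik(tr, x2, spj), tolerance = 1e-6)
})

test_that("doubling the grid resolution barely changes the likelihood", {
  tr <- simulate_pure_birth_tree(15, 60, seed = 31)
  x <- simulate_levy_traits(tr, levy_model_spec("BMJN", sigma2 = 0.5,
                                                lambda = 0.1, delta = 3,
                                                sigma_tip = 0.3), seed = 32)
  sp <- levy_model_spec("BMJN", sigma2 = 0.5, lambda = 0.1, delta = 3,
                        sigma_tip = 0.3)
  l1 <- levy_reml_loglik(tr, x, sp, grid_size = 1024)
  l2 <- levy_reml_loglik(tr, x, sp, grid_size = 2048)
  expect_lt(abs(l2 - l1), 1e-3)
})

test_that("the grid extent covers wide increment densities automatically", {
  tr <- tree_from_text("(A:60,B:60);")
  x <- trait_of(A = -0.1, B = 0.1)  # tiny data span, huge diffusion
  sp <- levy_model_spec("BM", sigma2 = 10, sigma_tip = 0.1)
  ll <- levy_reml_loglik(tr, x, sp, grid_size = 1024, pad = 2)
  expect_equal(ll, reml_gaussian_loglik(tr, x, sp), tolerance = 1e-3)
})
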