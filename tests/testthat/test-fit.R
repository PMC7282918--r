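test_that("Akaike weights follow the closed-form formula", {
  mk_fit <- function(model, aic) {
    k <- length(levyshift:::.levy_model_params[[model]])
    structure(list(model = model, class = levyshift:::model_class(model),
                   params = list(), loglik = (2 * k - aic) / 2, k = k,
                   aic = aic, converged = TRUE, n = 10),
              class = "levy_fit")
  }
  cmp <- aic_weights(list(mk_fit("BM", 100), mk_fit("OU", 102),
                          mk_fit("EB", 104)))
  expect_equal(cmp$models$weight, c(0.6652, 0.2447, 0.0900),
               tolerance = 1e-3)
  expect_equal(sum(cmp$models$weight), 1, tolerance = 1e-9)

  # equal AICs give uniform weights
  cmp2 <- aic_weights(list(mk_fit("BM", 50), mk_fit("OU", 50),
                           mk_fit("EB", 50)))
  expect_equal(cmp2$models$weight, rep(1 / 3, 3))

  # pulsed class weight is the maximum over jump models, not the sum
  jumps <- levyshift:::jump_models()
  target <- c(0.30, 0.25, 0.10, 0.05, 0.02, 0.01)
  rest <- 1 - sum(target)
  aics <- -2 * log(c(target, rest))  # weights proportional to exp(-aic/2)
  fits <- c(purrr::map2(jumps, aics[1:6], mk_fit), list(mk_fit("BM",
                                                               aics[7])))
  cmp3 <- aic_weights(fits)
  pw <- cmp3$classes$weight[cmp3$classes$class == "pulsed"]
  expect_equal(pw, 0.30, tolerance = 1e-9)
})

test_that("non-converged fits are refused unless overridden", {
  f1 <- structure(list(model = "BM", class = "BM", params = list(),
                       loglik = -10, k = 2, aic = 24, converged = TRUE,
                       n = 10), class = "levy_fit")
  f2 <- structure(list(model = "OU", class = "OU", params = list(),
                       loglik = -9, k = 3, aic = 24, converged = FALSE,
                       n = 10), class = "levy_fit")
  expect_error(aic_weights(list(f1, f2)), "non-converged")
  expect_s3_class(aic_weights(list(f1, f2), allow_nonconverged = TRUE),
                  "model_comparison")
})

test_that("the two-fold selection rule picks classes or calls it open", {
  tbl <- tibble::tibble(class = c("pulsed", "BM", "OU", "EB"),
                        weight = c(0.60, 0.20, 0.12, 0.08))
  expect_equal(select_best(tbl), "pulsed")
  tbl2 <- tibble::tibble(class = c("pulsed", "BM", "OU", "EB"),
                         weight = c(0.45, 0.30, 0.15, 0.10))
  expect_equal(select_best(tbl2), "inconclusive")
  # the CTL-like row: overwhelming pulsed support
  tbl3 <- tibble::tibble(class = c("pulsed", "BM", "OU", "EB"),
                         weight = c(0.979, 0.002, 0, 0))
  expect_equal(select_best(tbl3), "pulsed")
})

test_that("nested richer models never fit worse than their special case", {
  tr <- simulate_pure_birth_tree(20, 60, seed = 41)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1,
                                                sigma_tip = 0.2), seed = 42)
  bm <- fit_model(tr, x, "BM", restarts = 3, seed = 1)
  for (m in c("OU", "EB", "BMJN")) {
    rich <- fit_model(tr, x, m, restarts = 3, grid_size = 512, seed = 1)
    expect_gte(rich$loglik, bm$loglik - 1e-4)
  }
})

test_that("BM rate is recovered on simulated data", {
  fits <- lapply(1:5, function(i) {
    tr <- simulate_pure_birth_tree(100, 60, seed = 43 + i)
    x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1,
                                                  sigma_tip = 0.1),
                              seed = 143 + i)
    fit_model(tr, x, "BM", restarts = 2, seed = 2)
  })
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  s2 <- vapply(fits, function(f) f$params$sigma2, numeric(1))
  expect_equal(median(s2), 1, tolerance = 0.2)
  f <- fits[[1]]
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
})

test_that("EB fitted on BM data sits near the BM boundary", {
  tr <- simulate_pure_birth_tree(40, 60, seed = 45)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1,
                                                sigma_tip = 0.1), seed = 46)
  f <- fit_model(tr, x, "EB", restarts = 3, seed = 3)
  expect_lt(abs(f$params$r), 0.02)
})

test_that("fitted tip noise tracks the intraspecific noise level", {
  # replicate measurements per species feed the species means; the fitted
  # sigma_tip should track the (varying) true noise across datasets
  res <- vapply(1:20, function(i) {
    true_st <- 0.5 + 2.5 * (i - 1) / 19
    tr <- simulate_pure_birth_tree(50, 60, seed = 120 + i)
    x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1),
                              seed = 220 + i)
    # 3 replicates per species, averaged: effective noise true_st/sqrt(3)
    set.seed(320 + i)
    x$value <- x$value + rnorm(nrow(x), 0, true_st / sqrt(3))
    f <- fit_model(tr, x, "BM", restarts = 2, seed = 420 + i)
    c(true_st, f$params$sigma_tip)
  }, numeric(2))
  expect_gt(cor(res[1, ], res[2, ], method = "spearman"), 0.5)
})

test_that("tidy and glance methods expose fit results", {
  tr <- simulate_pure_birth_tree(12, 60, seed = 47)
  x <- simulate_levy_traits(tr, levy_model_spec("BM", sigma2 = 1), seed = 48)
  f <- fit_model(tr, x, "BM", restarts = 2, seed = 4)
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("sigma2", "sigma_tip"))
  gl <- glance(f)
  expect_equal(gl$model, "BM")
  expect_equal(gl$k, 2)
})
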