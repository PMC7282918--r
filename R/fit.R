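# parameter transforms: positive parameters are optimised on the log scale;
# the EB exponent r (<= 0) as log(-r)
.par_lower <- -18
.par_upper <- 12

par_to_natural <- function(model, theta) {
  pars <- .levy_model_params[[model]]
  out <- as.list(exp(theta))
  names(out) <- pars
  if ("r" %in% pars) out$r <- -exp(theta[match("r", pars)])
  out
}

natural_to_par <- function(model, vals) {
  pars <- .levy_model_params[[model]]
  th <- vapply(pars, function(p) {
    v <- vals[[p]]
    if (p == "r") log(max(-v, 1e-8)) else log(max(v, 1e-8))
  }, numeric(1))
  pmin(pmax(th, .par_lower), .par_upper)
}

spec_from_params <- function(model, vals) {
  do.call(levy_model_spec, c(list(model = model), vals))
}

# data-driven starting values
initial_params <- function(model, tree, trait) {
  x <- match_trait_to_tree(tree, trait)
  s2 <- max(bm_sigma2_hat(tree, trait), 1e-8)
  vx <- max(stats::var(unname(x)), 1e-8)
  depth <- tree_depth(tree)
  st <- sqrt(0.05 * vx)
  init <- list(sigma_tip = st)
  if (model %in% c("BM", "OU", "EB", "BMJN", "BMNIG")) init$sigma2 <- s2
  if (model == "OU") init$alpha <- 0.5 / depth
  if (model %in% c("EB", "EBJN", "EBNIG")) init$r <- -0.5 / depth
  if (model %in% c("JN", "BMJN", "EBJN")) {
    lam <- 0.05
    init$lambda <- lam
    init$delta <- sqrt(s2 / lam)
  }
  if (model %in% c("NIG", "BMNIG", "EBNIG")) {
    init$alpha_nig <- 1
    init$delta_nig <- s2
  }
  if (model %in% c("BMJN", "BMNIG")) {
    # split the rate estimate between the diffusive and jump parts
    init$sigma2 <- s2 / 2
    if (!is.null(init$delta)) init$delta <- sqrt(s2 / (2 * init$lambda))
    if (!is.null(init$delta_nig)) init$delta_nig <- s2 / 2
  }
  init[.levy_model_params[[model]]]
}

#' Fit one trait-evolution model by REML
#'
#' Maximises the REML log-likelihood of the named model over its free
#' parameters (the tip-noise SD is always free; the root state is profiled
#' out and not counted). Gaussian models (BM, OU, EB) use the exact
#' contrasts likelihood; pulsed models use the grid/FFT pruning likelihood.
#' Optimisation is bounded quasi-Newton (L-BFGS-B) on log-transformed
#' parameters with multi-start from dispersed initial values.
#'
#' @param tree Time tree.
#' @param trait Trait values for all tips.
#' @param model One of [levy_models()].
#' @param restarts Number of optimiser starts (default 10; the first is
#'   data-driven, the rest are dispersed perturbations of it).
#' @param grid_size FFT grid size for pulsed models.
#' @param seed Optional seed controlling the dispersed restarts.
#' @return A `levy_fit` object: fitted parameters, REML log-likelihood,
#'   parameter count `k`, `AIC = 2k - 2 logLik` and convergence
#'   diagnostics. [tidy()] and [glance()] methods are provided.
#' @export
fit_model <- function(tree, trait, model, restarts = 10, grid_size = 1024,
                      seed = NULL) {
  if (!model %in% levy_models()) {
    stop("unknown model '", model, "'", call. = FALSE)
  }
  x <- match_trait_to_tree(tree, trait)
  if (length(x) < 3) stop("need at least 3 tips to fit a model",
                          call. = FALSE)
  gaussian <- model %in% c("BM", "OU", "EB")
  # resolution floor: a pulsed-model density narrower than the FFT grid
  # spacing cannot be represented, so sigma_tip is bounded below by
  # 1.5 * dx for those models (the Gaussian contrasts likelihood is exact
  # and needs no floor)
  lower <- rep(.par_lower, length(.levy_model_params[[model]]))
  if (!gaussian) {
    span <- diff(range(x))
    if (span <= 0) span <- max(abs(x), 1)
    dx <- span * (1 + 2 * 2) / grid_size  # pad = 2 on each side
    lower[match("sigma_tip", .levy_model_params[[model]])] <-
      log(1.5 * dx)
  }
  negloglik <- function(theta) {
    vals <- par_to_natural(model, theta)
    spec <- tryCatch(spec_from_params(model, vals), error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    ll <- tryCatch({
      if (gaussian) reml_gaussian_loglik(tree, x, spec)
      else levy_reml_loglik(tree, x, spec, grid_size = grid_size,
                            check_mass = FALSE)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  init <- initial_params(model, tree, x)
  theta0 <- pmax(natural_to_par(model, init), lower)
  np <- length(theta0)
  starts <- with_seed(seed, {
    rbind(theta0,
          if (restarts > 1) {
            t(replicate(restarts - 1,
                        pmin(pmax(theta0 + stats::rnorm(np, 0, 1.5),
                                  lower), .par_upper)))
          })
  })
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(starts[i, ], negloglik, method = "L-BFGS-B",
                   lower = lower, upper = .par_upper,
                   control = list(factr = 1e7, maxit = 300)),
      error = function(e) NULL)
  }
  ok <- !vapply(runs, is.null, logical(1))
  runs <- runs[ok]
  if (length(runs) == 0) {
    stop("all optimiser restarts failed for model ", model, call. = FALSE)
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  conv <- vapply(runs, function(r) r$convergence == 0, logical(1))
  # prefer converged restarts; among those, the best likelihood
  pick <- if (any(conv)) which(conv)[which.min(vals[conv])] else
    which.min(vals)
  best <- runs[[pick]]
  params <- par_to_natural(model, best$par)
  loglik <- -best$value
  k <- length(.levy_model_params[[model]])
  restart_tbl <- tibble::tibble(
    restart = seq_along(runs),
    loglik = -vals,
    converged = conv)
  structure(list(model = model,
                 class = model_class(model),
                 params = params,
                 loglik = loglik,
                 k = k,
                 aic = 2 * k - 2 * loglik,
                 converged = any(conv),
                 restarts = restart_tbl,
                 grid_size = if (gaussian) NA_integer_ else grid_size,
                 n = length(x)),
            class = "levy_fit")
}

#' @export
print.levy_fit <- function(x, ...) {
  cat("<levy_fit> ", x$model, " (", x$class, " class), n = ", x$n, "\n",
      "  logLik = ", format(x$loglik, digits = 8), ", k = ", x$k,
      ", AIC = ", format(x$aic, digits = 8),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  for (p in names(x$params)) {
    cat("  ", p, " = ", format(x$params[[p]], digits = 5), "\n", sep = "")
  }
  invisible(x)
}

#' Fit every candidate model to one trait
#'
#' Convenience wrapper running [fit_model()] for each requested model on
#' the same tree and trait.
#'
#' @inheritParams fit_model
#' @param models Character vector of model names (default all nine).
#' @return A named list of `levy_fit` objects, class `levy_fit_list`.
#' @export
fit_all_models <- function(tree, trait, models = levy_models(),
                           restarts = 10, grid_size = 1024, seed = NULL) {
  fits <- purrr::imap(stats::setNames(seq_along(models), models),
                      function(i, m) {
                        fit_model(tree, trait, m, restarts = restarts,
                                  grid_size = grid_size,
                                  seed = if (is.null(seed)) NULL else
                                    seed + i)
                      })
  names(fits) <- models
  structure(fits, class = "levy_fit_list")
}
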