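#' REML log-likelihood of a Gaussian trait-evolution model
#'
#' Computes the restricted (contrasts) log-likelihood of BM, OU or EB with
#' Gaussian tip noise: the tree is first rescaled according to the model
#' (identity for BM), then phylogenetic independent contrasts are formed
#' with `sigma_tip^2` added to every tip's terminal variance. The sum of
#' contrast log-densities equals the full multivariate-normal likelihood
#' with the unknown root state (grand mean) profiled out; polytomies are
#' handled by merging their children sequentially.
#'
#' @param tree Time tree.
#' @param trait `scaled_trait` tibble or named numeric vector covering all
#'   tips.
#' @param spec A [levy_model_spec()] for BM, OU or EB.
#' @return The REML log-likelihood (scalar).
#' @export
reml_gaussian_loglik <- function(tree, trait, spec) {
  stopifnot(inherits(spec, "levy_model_spec"))
  if (!spec$model %in% c("BM", "OU", "EB")) {
    stop("reml_gaussian_loglik handles the Gaussian models BM/OU/EB; use ",
         "levy_reml_loglik for pulsed models", call. = FALSE)
  }
  x <- match_trait_to_tree(tree, trait)
  if (length(x) < 2) {
    stop("need at least 2 tips for a REML contrast", call. = FALSE)
  }
  tr <- rescale_for_model(tree, spec)
  arr <- tree_arrays(tr)
  bm_reml_loglik_cpp(arr$edge, arr$edge_length, arr$postorder, arr$n_tip,
                     unname(x), spec$sigma2, spec$sigma_tip)
}

# dense-matrix oracle: restricted likelihood from the full tip covariance
# V = sigma2 * C + sigma_tip^2 I with the GLS mean profiled out; used as an
# independent cross-check of the contrasts recursion
reml_gaussian_loglik_dense <- function(tree, trait, spec) {
  x <- unname(match_trait_to_tree(tree, trait))
  tr <- rescale_for_model(tree, spec)
  V <- spec$sigma2 * ape::vcv(tr) + diag(spec$sigma_tip^2, length(x))
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Vi %*% one)
  mu <- as.numeric(t(one) %*% Vi %*% x) / denom
  resid <- x - mu
  quad <- as.numeric(t(resid) %*% Vi %*% resid)
  as.numeric(-0.5 * ((n - 1) * log(2 * pi) + determinant(V)$modulus +
                       log(denom) + quad))
}

# phylogenetic independent contrasts under unit-rate BM (variance in branch
# length units); returns contrast values and their variances
pic_contrasts <- function(tree, trait, sigma_tip = 0) {
  x <- match_trait_to_tree(tree, trait)
  arr <- tree_arrays(tree)
  n_tip <- arr$n_tip
  nn <- n_tip + tree$Nnode
  xv <- numeric(nn)
  vv <- numeric(nn)
  has <- logical(nn)
  xv[seq_len(n_tip)] <- unname(x)
  vv[seq_len(n_tip)] <- sigma_tip^2
  has[seq_len(n_tip)] <- TRUE
  contrasts <- numeric(0)
  variances <- numeric(0)
  for (i in arr$postorder) {
    p <- arr$edge[i, 1]
    c <- arr$edge[i, 2]
    xc <- xv[c]
    vc <- vv[c] + arr$edge_length[i]
    if (!has[p]) {
      xv[p] <- xc
      vv[p] <- vc
      has[p] <- TRUE
    } else {
      vs <- vv[p] + vc
      contrasts <- c(contrasts, xc - xv[p])
      variances <- c(variances, vs)
      xv[p] <- (vc * xv[p] + vv[p] * xc) / vs
      vv[p] <- vv[p] * vc / vs
    }
  }
  tibble::tibble(contrast = contrasts, variance = variances)
}

# quick REML point estimate of the BM rate (sigma_tip = 0)
bm_sigma2_hat <- function(tree, trait) {
  pc <- pic_contrasts(tree, trait)
  mean(pc$contrast^2 / pc$variance)
}

#' REML log-likelihood of a pulsed (Levy) trait-evolution model
#'
#' Pruning likelihood in which every node's conditional density (of its
#' subtree's data given the node state) lives on a regular grid. Branch
#' propagation convolves with the branch increment density, obtained by
#' inverting the characteristic function exp(t psi(k)) by FFT; EB variants
#' first rescale branch lengths. Tip observations enter through an exact
#' spectral phase shift with Normal(0, sigma_tip^2) noise folded in, and
#' the root state is integrated against a flat prior, which yields the
#' REML-type likelihood (for Gaussian models this reproduces
#' [reml_gaussian_loglik()] to grid accuracy). Deterministic given grid
#' settings.
#'
#' @param tree Time tree.
#' @param trait Trait values for all tips.
#' @param spec A [levy_model_spec()]; any of the nine models is accepted
#'   (Gaussian models are evaluated on the same grid machinery, OU via its
#'   branch rescaling).
#' @param grid_size Number of grid points; must be a power of two.
#' @param pad Grid extent padding: the grid spans the data range extended by
#'   `pad` times the data span on each side. The default of 2 balances
#'   extent (guarded by the mass check) against resolution; densities
#'   narrower than the grid spacing are not representable, which is why
#'   [fit_model()] floors `sigma_tip` at a small multiple of the spacing
#'   for pulsed models.
#' @param check_mass If `TRUE`, error when a branch increment density leaks
#'   more than `1e-4` of its mass into the outer 5% of the grid (a sign the
#'   extent is too small).
#' @param refine If `TRUE`, double `grid_size` until the log-likelihood
#'   changes by less than `1e-3`, capped at 8192 points.
#' @return The log-likelihood (scalar).
#' @export
levy_reml_loglik <- function(tree, trait, spec, grid_size = 1024, pad = 2,
                             check_mass = TRUE, refine = FALSE) {
  stopifnot(inherits(spec, "levy_model_spec"))
  if (bitwAnd(grid_size, grid_size - 1L) != 0 || grid_size < 64) {
    stop("grid_size must be a power of two >= 64", call. = FALSE)
  }
  x <- match_trait_to_tree(tree, trait)
  tr <- rescale_for_model(tree, spec)
  arr <- tree_arrays(tr)
  xs <- unname(x)
  span <- diff(range(xs))
  if (span <= 0) span <- max(abs(xs), 1)
  # the extent must hold both the data (plus padding) and the widest branch
  # increment density of the model being evaluated
  sd_max <- sqrt(increment_variance_rate(spec) * max(arr$edge_length) +
                   spec$sigma_tip^2)
  half <- max(pad * span, 6 * sd_max)
  x0 <- min(xs) - half
  x1 <- max(xs) + half
  eval_grid <- function(N) {
    dx <- (x1 - x0) / N
    ll <- levy_pruning_loglik_cpp(arr$edge, arr$edge_length, arr$postorder,
                                  arr$n_tip, xs, spec$sigma_tip,
                                  jump_type_code(spec$model), spec$sigma2,
                                  spec$lambda, spec$delta, spec$alpha_nig,
                                  spec$delta_nig, as.integer(N), x0, dx,
                                  if (check_mass) 1e-4 else 0)
    if (!is.finite(ll)) {
      stop("non-finite pulsed-model likelihood (grid collapse); try a ",
           "larger grid_size or pad", call. = FALSE)
    }
    ll
  }
  ll <- eval_grid(grid_size)
  if (refine) {
    N <- grid_size
    while (N < 8192) {
      N <- N * 2
      ll2 <- eval_grid(N)
      if (abs(ll2 - ll) < 1e-3) {
        ll <- ll2
        break
      }
      ll <- ll2
    }
  }
  ll
}
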