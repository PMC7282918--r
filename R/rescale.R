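#' Rescale branch lengths so BM reproduces the single-optimum OU covariance
#'
#' On an ultrametric tree of depth T, an OU process with pull `alpha`
#' started at the root has tip covariance
#' sigma2/(2 alpha) e^(-2 alpha (T - s)) (1 - e^(-2 alpha s)) for tips whose
#' most recent common ancestor sits at height s. Mapping every node height h
#' to h' = (e^(-2 alpha (T - h)) - e^(-2 alpha T)) / (2 alpha) turns that
#' covariance into plain Brownian motion on the rescaled tree; the map is
#' continuous in alpha with h' -> h as alpha -> 0.
#'
#' @param tree Ultrametric time tree.
#' @param alpha OU pull (1 / time), >= 0.
#' @return The tree with rescaled branch lengths (no longer in time units).
#' @export
rescale_branches_ou <- function(tree, alpha) {
  stopifnot(alpha >= 0)
  check_ultrametric(tree, context = "OU rescaling: tree")
  if (alpha < 1e-12) return(tree)
  h <- node_heights(tree)
  T <- max(h[seq_len(ape::Ntip(tree))])
  hprime <- exp(-2 * alpha * T) * expm1(2 * alpha * h) / (2 * alpha)
  tree$edge.length <- hprime[tree$edge[, 2]] - hprime[tree$edge[, 1]]
  tree
}

#' Rescale branch lengths under the early-burst model
#'
#' Under EB the instantaneous Brownian rate decays as e^(r t) with t the
#' absolute time from the root and r <= 0 ("early burst": fast first, slow
#' later). A branch spanning times [t1, t2] therefore accumulates variance
#' proportional to (e^(r t2) - e^(r t1)) / r, which becomes its rescaled
#' length; r = 0 leaves the tree unchanged.
#'
#' @param tree Time tree.
#' @param r Rate-decay exponent (1 / time), must be <= 0.
#' @return The tree with rescaled branch lengths.
#' @export
rescale_branches_eb <- function(tree, r) {
  if (r > 0) {
    stop("early-burst exponent r must be <= 0 (r > 0 would be exponential ",
         "acceleration, excluded by the model definition)", call. = FALSE)
  }
  if (abs(r) < 1e-12) return(tree)
  h <- node_heights(tree)
  t1 <- h[tree$edge[, 1]]
  t2 <- h[tree$edge[, 2]]
  tree$edge.length <- exp(r * t1) * expm1(r * (t2 - t1)) / r
  tree
}

# rescale a tree according to the Gaussian part of a model spec
rescale_for_model <- function(tree, spec) {
  switch(spec$model,
         OU = rescale_branches_ou(tree, spec$alpha),
         EB = ,
         EBJN = ,
         EBNIG = rescale_branches_eb(tree, spec$r),
         tree)
}
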