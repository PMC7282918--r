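#' Effective sample size of an MCMC scalar series
#'
#' Autocorrelation-time-based ESS using Geyer's initial positive sequence:
#' the integrated autocorrelation time is 1 + 2 * sum of autocorrelations,
#' truncated at the first non-positive sum of adjacent pairs. The estimate
#' is capped at the series length; a constant series is reported as length
#' n with a degeneracy flag, and negative-autocorrelation series that
#' exceed n are capped with a flag (attribute `"flag"`: `"ok"`,
#' `"degenerate"` or `"capped"`).
#'
#' @param series Numeric vector, length >= 10.
#' @return The effective sample size (scalar, <= length of the series).
#' @export
ess <- function(series) {
  n <- length(series)
  if (n < 10) stop("series must have length >= 10", call. = FALSE)
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) {
    out <- n
    attr(out, "flag") <- "degenerate"
    return(out)
  }
  lag_max <- min(n - 2, 2000)
  rho <- as.numeric(stats::acf(series, lag.max = lag_max,
                               plot = FALSE)$acf)
  # pair sums Gamma_t = rho_{2t} + rho_{2t+1}; stop at first non-positive
  npair <- floor(length(rho) / 2)
  gam <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  stop_at <- which(gam <= 0)[1]
  if (!is.na(stop_at)) gam <- gam[seq_len(stop_at - 1)]
  tau <- -1 + 2 * sum(gam)
  if (!is.finite(tau) || tau <= 0) {
    out <- n
    attr(out, "flag") <- "capped"
    return(out)
  }
  est <- n / tau
  if (est > n) {
    out <- n
    attr(out, "flag") <- "capped"
  } else {
    out <- est
    attr(out, "flag") <- "ok"
  }
  out
}

# instantaneous rate per edge at given absolute times under one
# configuration; NA where the edge is not alive
edge_rate_matrix <- function(tree, config, times_abs,
                             arr = tree_arrays(tree)) {
  segs <- paint_regimes(tree, config, arr = arr)
  E <- nrow(arr$edge)
  out <- matrix(NA_real_, E, length(times_abs))
  eps <- 1e-9 * max(arr$depth, 1)
  for (e in seq_len(E)) {
    s <- segs[[e]]
    lo <- arr$t_start[e]
    hi <- lo + arr$edge_length[e]
    alive <- times_abs >= lo - eps & times_abs <= hi + eps
    if (!any(alive)) next
    tt <- pmin(pmax(times_abs[alive], lo), hi)
    idx <- findInterval(tt, s[, "from"], rightmost.closed = TRUE)
    idx[idx < 1] <- 1
    out[e, alive] <- s[idx, "beta"] * exp(s[idx, "b"] * (tt - s[idx, "t0"]))
  }
  out
}

# edges whose child node lies inside the clade spanned by `tips`
clade_edges <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  if (length(tips) < 2) stop("clade needs >= 2 tips", call. = FALSE)
  mrca <- ape::getMRCA(tree, tips)
  desc <- c(mrca, descendant_nodes(tree, mrca))
  which(tree$edge[, 1] %in% desc)
}

# all descendant nodes of `node` (internal + tips), plain BFS
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  frontier <- node
  while (length(frontier) > 0) {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids[kids > ape::Ntip(tree)]
  }
  unique(out)
}

sample_config <- function(samples_row, events, id) {
  ev <- events[events$sample == id, , drop = FALSE]
  shift_configuration(
    if (nrow(ev) > 0) ev[c("edge", "time", "beta", "b")] else NULL,
    root_beta = samples_row$root_beta,
    root_b = samples_row$root_b)
}

#' Posterior mean evolutionary rate through time
#'
#' For each time point, averages the instantaneous rate beta(t) over the
#' lineages alive at that time (optionally restricted to a clade), then
#' summarises over posterior samples by the mean and a central credible
#' band. Time points predating the clade's origin are reported as `NA`
#' (absent), not zero.
#'
#' @param sample A `rateshift_sample`.
#' @param clade Optional character vector of tip labels delimiting a clade
#'   (its MRCA's subtree); default uses all lineages.
#' @param grid Number of time points (default 50).
#' @param burnin Fraction of initial samples to discard.
#' @param max_samples Cap on posterior samples used (evenly subsampled).
#' @param level Width of the central credible band (default 0.90).
#' @return A tibble (class `rate_through_time`) with columns
#'   `time_before_present`, `rate_mean`, `rate_lower`, `rate_upper`,
#'   `n_lineages`.
#' @export
rate_through_time <- function(sample, clade = NULL, grid = 50,
                              burnin = 0.1, max_samples = 500,
                              level = 0.90) {
  stopifnot(inherits(sample, "rateshift_sample"))
  tree <- sample$tree
  depth <- tree_depth(tree)
  times_abs <- seq(0, depth, length.out = grid)
  kept <- retain_samples(sample, burnin)
  ids <- kept$samples$sample
  if (length(ids) > max_samples) {
    ids <- ids[round(seq(1, length(ids), length.out = max_samples))]
  }
  sel <- if (is.null(clade)) seq_len(nrow(tree$edge)) else
    clade_edges(tree, clade)
  arr <- tree_arrays(tree)
  keep_rows <- match(ids, kept$samples$sample)
  mat <- matrix(NA_real_, length(ids), grid)
  n_lin <- rep(NA_integer_, grid)
  for (i in seq_along(ids)) {
    row <- kept$samples[keep_rows[i], , drop = FALSE]
    cfg <- sample_config(row, kept$events, ids[i])
    rates <- edge_rate_matrix(tree, cfg, times_abs,
                              arr = arr)[sel, , drop = FALSE]
    mat[i, ] <- colMeans(rates, na.rm = TRUE)
    if (i == 1) n_lin <- colSums(!is.na(rates))
  }
  mat[is.nan(mat)] <- NA_real_
  a <- (1 - level) / 2
  out <- tibble::tibble(
    time_before_present = depth - times_abs,
    rate_mean = colMeans(mat, na.rm = TRUE),
    rate_lower = apply(mat, 2, stats::quantile, probs = a, na.rm = TRUE),
    rate_upper = apply(mat, 2, stats::quantile, probs = 1 - a,
                       na.rm = TRUE),
    n_lineages = n_lin)
  out$rate_mean[out$n_lineages == 0] <- NA_real_
  out$rate_lower[out$n_lineages == 0] <- NA_real_
  out$rate_upper[out$n_lineages == 0] <- NA_real_
  class(out) <- c("rate_through_time", class(out))
  out
}

#' Posterior mean rate per branch (phylorate export)
#'
#' Time-averaged instantaneous rate of each branch (accumulated variance
#' divided by branch duration), summarised over posterior samples; the
#' numbers behind a phylorate plot.
#'
#' @param sample A `rateshift_sample`.
#' @param burnin Fraction of initial samples to discard.
#' @param max_samples Cap on posterior samples used.
#' @param level Central credible band width.
#' @return A tibble with one row per edge: `edge`, `parent`, `child`,
#'   `mean_rate`, `rate_lower`, `rate_upper`.
#' @export
branch_rates <- function(sample, burnin = 0.1, max_samples = 1000,
                         level = 0.90) {
  stopifnot(inherits(sample, "rateshift_sample"))
  tree <- sample$tree
  kept <- retain_samples(sample, burnin)
  ids <- kept$samples$sample
  if (length(ids) > max_samples) {
    ids <- ids[round(seq(1, length(ids), length.out = max_samples))]
  }
  E <- nrow(tree$edge)
  arr <- tree_arrays(tree)
  keep_rows <- match(ids, kept$samples$sample)
  acc <- matrix(NA_real_, length(ids), E)
  for (i in seq_along(ids)) {
    row <- kept$samples[keep_rows[i], , drop = FALSE]
    cfg <- sample_config(row, kept$events, ids[i])
    acc[i, ] <- effective_branch_lengths(tree, cfg, arr = arr) /
      tree$edge.length
  }
  a <- (1 - level) / 2
  tibble::tibble(edge = seq_len(E), parent = tree$edge[, 1],
                 child = tree$edge[, 2],
                 label = ifelse(tree$edge[, 2] <= ape::Ntip(tree),
                                tree$tip.label[tree$edge[, 2]],
                                NA_character_),
                 mean_rate = colMeans(acc),
                 rate_lower = apply(acc, 2, stats::quantile, probs = a),
                 rate_upper = apply(acc, 2, stats::quantile,
                                    probs = 1 - a))
}

#' Write a Newick string annotated with per-branch rates
#'
#' Emits the tree with each branch length followed by a comment of the form
#' `[&rate=...]`, the conventional annotation consumed by tree viewers for
#' phylorate-style colouring.
#'
#' @param tree Time tree.
#' @param rates A tibble from [branch_rates()] (or any tibble with `edge`
#'   and `mean_rate`).
#' @param path Optional file path; when given the string is also written
#'   there.
#' @return The annotated Newick string, invisibly when `path` is given.
#' @export
annotated_newick <- function(tree, rates, path = NULL) {
  rate_by_child <- stats::setNames(rates$mean_rate,
                                   tree$edge[rates$edge, 2])
  edge_by_child <- stats::setNames(seq_len(nrow(tree$edge)),
                                   tree$edge[, 2])
  n_tip <- ape::Ntip(tree)
  build <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    inner <- if (length(kids) == 0) {
      tree$tip.label[node]
    } else {
      paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
             ")")
    }
    e <- edge_by_child[as.character(node)]
    if (is.na(e)) return(inner)  # root
    paste0(inner, ":", format(tree$edge.length[e], digits = 10),
           "[&rate=", format(rate_by_child[as.character(node)],
                             digits = 6), "]")
  }
  s <- paste0(build(n_tip + 1), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
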