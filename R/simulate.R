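#' Simulate an ultrametric pure-birth tree of fixed depth
#'
#' Draws a Yule (pure-birth) tree conditioned on the number of tips and
#' rescales all branch lengths so the root-to-tip depth equals `depth`
#' (time units; the shipped analyses use millions of years).
#'
#' @param n_tips Number of tips, >= 3.
#' @param depth Root-to-tip depth, > 0.
#' @param seed Optional integer; fixing it makes the tree reproducible.
#' @return An ultrametric [ape::phylo] tree with `n_tips` tips.
#' @export
simulate_pure_birth_tree <- function(n_tips, depth, seed = NULL) {
  stopifnot(n_tips >= 3, depth > 0)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length * depth / tree_depth(tree)
    tree
  })
}

# one Michael-Schucany-Haas inverse-Gaussian draw per (mean, shape) pair
rinvgauss <- function(n, mean, shape) {
  y <- stats::rnorm(n)^2
  x <- mean + mean^2 * y / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  z <- stats::runif(n)
  ifelse(z <= mean / (mean + x), x, mean^2 / x)
}

# symmetric centred NIG increment over effective time t:
# X | Z ~ N(0, Z), Z ~ IG(mean = delta t / alpha, shape = (delta t)^2)
rnig_increment <- function(n, t, alpha_nig, delta_nig) {
  dt <- delta_nig * t
  if (alpha_nig <= 0 || any(dt <= 0)) return(numeric(n))
  z <- rinvgauss(n, mean = dt / alpha_nig, shape = dt^2)
  stats::rnorm(n, 0, sqrt(z))
}

#' Simulate continuous traits under a Levy-class evolution model
#'
#' Starting from `root_state`, draws the increment of the chosen process
#' along every branch (in the tree's stored edge order, parents before
#' children, so a fixed seed reproduces every branch's draws independently
#' of traversal implementation) and adds Gaussian tip noise at the tips.
#' OU is simulated exactly through its Gaussian transition; EB variants act
#' through the early-burst branch rescaling; JN jumps are compound Poisson
#' with Normal jump sizes; NIG increments come from the symmetric
#' normal-inverse-Gaussian distribution.
#'
#' @param tree Time tree.
#' @param spec A [levy_model_spec()].
#' @param seed Optional integer seed.
#' @param root_state Trait value at the root (default 0; REML inference is
#'   invariant to it).
#' @return A `scaled_trait` tibble (`species`, `value`).
#' @export
simulate_levy_traits <- function(tree, spec, seed = NULL, root_state = 0) {
  stopifnot(inherits(spec, "levy_model_spec"))
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    n_node <- n_tip + tree$Nnode
    state <- numeric(n_node)
    state[n_tip + 1] <- root_state
    pre <- rev(postorder_index(tree))
    tlen <- tree$edge.length
    eff <- if (is_eb_variant(spec$model)) {
      rescale_branches_eb(tree, spec$r)$edge.length
    } else {
      tlen
    }
    jt <- jump_type_code(spec$model)
    for (i in pre) {
      p <- tree$edge[i, 1]
      c <- tree$edge[i, 2]
      t <- eff[i]
      if (spec$model == "OU" && spec$alpha > 0) {
        a <- spec$alpha
        m <- spec$theta + (state[p] - spec$theta) * exp(-a * tlen[i])
        v <- spec$sigma2 * (1 - exp(-2 * a * tlen[i])) / (2 * a)
        state[c] <- m + stats::rnorm(1, 0, sqrt(v))
        next
      }
      inc <- spec$mu * t
      if (spec$sigma2 > 0) inc <- inc + stats::rnorm(1, 0, sqrt(spec$sigma2 * t))
      if (jt == 1L && spec$lambda > 0) {
        k <- stats::rpois(1, spec$lambda * t)
        if (k > 0) inc <- inc + stats::rnorm(1, 0, spec$delta * sqrt(k))
      } else if (jt == 2L) {
        inc <- inc + rnig_increment(1, t, spec$alpha_nig, spec$delta_nig)
      }
      state[c] <- state[p] + inc
    }
    tips <- state[seq_len(n_tip)]
    if (spec$sigma_tip > 0) {
      tips <- tips + stats::rnorm(n_tip, 0, spec$sigma_tip)
    }
    new_scaled_trait(tree$tip.label, tips, toxin = spec$model)
  })
}

#' Construct a rate-shift configuration
#'
#' A configuration is a root regime plus zero or more shift events. Each
#' event sits on an edge at an absolute time from the root and opens a new
#' regime with instantaneous rate beta(t) = beta * exp(b (t - t_shift)),
#' inherited by everything downstream until overridden by a nested shift.
#'
#' @param events A data frame with columns `edge` (row index into
#'   `tree$edge`), `time` (absolute time from the root), `beta`
#'   (initial rate, > 0) and `b` (rate-change exponent, 1/time), or `NULL`
#'   for a zero-shift configuration.
#' @param root_beta Root-regime initial rate (> 0).
#' @param root_b Root-regime exponent (default 0 = constant rate).
#' @return An object of class `shift_configuration`.
#' @export
shift_configuration <- function(events = NULL, root_beta = 1, root_b = 0) {
  if (is.null(events)) {
    events <- tibble::tibble(edge = integer(), time = numeric(),
                             beta = numeric(), b = numeric())
  }
  events <- tibble::as_tibble(events)
  stopifnot(all(c("edge", "time", "beta", "b") %in% names(events)),
            root_beta > 0, all(events$beta > 0))
  structure(list(events = events[c("edge", "time", "beta", "b")],
                 root_beta = root_beta, root_b = root_b),
            class = "shift_configuration")
}

#' @export
print.shift_configuration <- function(x, ...) {
  cat("<shift_configuration> ", nrow(x$events), " shift(s); root beta = ",
      format(x$root_beta, digits = 4), ", root b = ",
      format(x$root_b, digits = 4), "\n", sep = "")
  if (nrow(x$events) > 0) print(x$events)
  invisible(x)
}

# per-edge regime timeline induced by a configuration: for each edge, a
# matrix of segments (columns from, to, beta, b, t0); used by the
# effective-length and rate-through-time computations. Plain matrices:
# this runs once per posterior sample, so per-edge allocation must stay
# cheap.
paint_regimes <- function(tree, config, arr = tree_arrays(tree)) {
  E <- nrow(arr$edge)
  ev <- config$events
  has_events <- nrow(ev) > 0
  if (has_events) {
    if (any(ev$edge < 1 | ev$edge > E)) {
      stop("shift event on non-existent edge", call. = FALSE)
    }
    t_lo <- arr$t_start[ev$edge]
    t_hi <- t_lo + arr$edge_length[ev$edge]
    if (any(ev$time < t_lo - 1e-9 | ev$time > t_hi + 1e-9)) {
      stop("shift event time outside its edge", call. = FALSE)
    }
    ev_edge <- ev$edge
    ev_time <- ev$time
    ev_beta <- ev$beta
    ev_b <- ev$b
  }
  seglist <- vector("list", E)
  end_regime <- matrix(NA_real_, E, 3)  # beta, b, t0
  for (i in arr$preorder) {
    pe <- arr$parent_edge[i]
    reg <- if (pe > 0) end_regime[pe, ] else
      c(config$root_beta, config$root_b, 0)
    a <- arr$t_start[i]
    end <- a + arr$edge_length[i]
    if (has_events && any(sel <- ev_edge == i)) {
      ord <- order(ev_time[sel])
      ts <- ev_time[sel][ord]
      seg <- cbind(from = c(a, ts), to = c(ts, end),
                   beta = c(reg[1], ev_beta[sel][ord]),
                   b = c(reg[2], ev_b[sel][ord]),
                   t0 = c(reg[3], ts))
    } else {
      seg <- cbind(from = a, to = end, beta = reg[1], b = reg[2],
                   t0 = reg[3])
    }
    seglist[[i]] <- seg
    k <- nrow(seg)
    end_regime[i, ] <- seg[k, c("beta", "b", "t0")]
  }
  seglist
}

regime_segment_integral <- function(beta, b, t0, from, to) {
  ifelse(abs(b) < 1e-10,
         beta * (to - from),
         (beta / b) * (exp(b * (to - t0)) - exp(b * (from - t0))))
}

#' Accumulated trait variance per branch under a shift configuration
#'
#' Integrates the instantaneous rate beta(t) along every edge across its
#' regime segments, reducing rate-shifted Brownian motion to plain BM on a
#' tree whose "branch lengths" are these variance accumulations. With a
#' zero-shift, constant-rate configuration this is just `root_beta` times
#' the branch lengths.
#'
#' @param tree Time tree.
#' @param config A [shift_configuration()].
#' @param arr Precomputed edge arrays (internal use; defaults to deriving
#'   them from `tree`).
#' @return Numeric vector of per-edge variance accumulations, in
#'   `tree$edge` row order.
#' @export
effective_branch_lengths <- function(tree, config,
                                     arr = tree_arrays(tree)) {
  segs <- paint_regimes(tree, config, arr = arr)
  vapply(segs, function(s) {
    sum(regime_segment_integral(s[, "beta"], s[, "b"], s[, "t0"],
                                s[, "from"], s[, "to"]))
  }, numeric(1))
}

#' Simulate a trait under rate-shifted Brownian motion
#'
#' Brownian increments whose variance over each branch equals the integral
#' of the configuration's instantaneous rate along that branch, plus
#' optional Gaussian tip noise.
#'
#' @param tree Time tree.
#' @param config A [shift_configuration()].
#' @param sigma_tip Tip-noise SD (default 0).
#' @param seed Optional integer seed.
#' @param root_state Root trait value (default 0).
#' @return A `scaled_trait` tibble.
#' @export
simulate_shifted_bm <- function(tree, config, sigma_tip = 0, seed = NULL,
                                root_state = 0) {
  evar <- effective_branch_lengths(tree, config)
  if (any(evar < 0)) stop("negative accumulated variance", call. = FALSE)
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    state <- numeric(n_tip + tree$Nnode)
    state[n_tip + 1] <- root_state
    for (i in rev(postorder_index(tree))) {
      state[tree$edge[i, 2]] <- state[tree$edge[i, 1]] +
        stats::rnorm(1, 0, sqrt(evar[i]))
    }
    tips <- state[seq_len(n_tip)]
    if (sigma_tip > 0) tips <- tips + stats::rnorm(n_tip, 0, sigma_tip)
    new_scaled_trait(tree$tip.label, tips, toxin = "SHIFTED_BM")
  })
}
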