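# internal helpers

# run code with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# accept a scaled-trait tibble (species, value) or a named numeric vector
as_trait_vector <- function(trait) {
  if (is.data.frame(trait)) {
    if (!all(c("species", "value") %in% names(trait))) {
      stop("trait data frame must have columns 'species' and 'value'",
           call. = FALSE)
    }
    out <- stats::setNames(trait$value, trait$species)
  } else if (is.numeric(trait) && !is.null(names(trait))) {
    out <- trait
  } else {
    stop("trait must be a (species, value) data frame or a named numeric ",
         "vector", call. = FALSE)
  }
  if (anyNA(out) || any(!is.finite(out))) {
    stop("trait values must be finite and non-missing", call. = FALSE)
  }
  out
}

new_scaled_trait <- function(species, value, toxin = NA_character_,
                             scaling_constant = NA_real_) {
  out <- tibble::tibble(species = as.character(species),
                        value = as.numeric(value))
  attr(out, "toxin") <- toxin
  attr(out, "scaling_constant") <- scaling_constant
  class(out) <- c("scaled_trait", class(out))
  out
}

# match a trait to the tree's tip labels, erroring on mismatch
match_trait_to_tree <- function(tree, trait) {
  x <- as_trait_vector(trait)
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss) > 0) {
    stop("no trait value for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x[tree$tip.label]
}

node_heights <- function(tree) {
  ape::node.depth.edgelength(tree)
}

tree_depth <- function(tree) {
  h <- node_heights(tree)
  max(h[seq_len(ape::Ntip(tree))])
}

# postorder row indices of tree$edge (children before parents)
postorder_index <- function(tree) {
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}

# edge-table arrays shared by the C++ routines
tree_arrays <- function(tree) {
  po <- postorder_index(tree)
  h <- node_heights(tree)
  list(edge = tree$edge,
       edge_length = tree$edge.length,
       postorder = as.integer(po),
       preorder = as.integer(rev(po)),
       parent_edge = {
         pe <- match(tree$edge[, 1], tree$edge[, 2])
         pe[is.na(pe)] <- 0L
         as.integer(pe)
       },
       t_start = h[tree$edge[, 1]],
       n_tip = ape::Ntip(tree),
       depth = max(h[seq_len(ape::Ntip(tree))]))
}

check_ultrametric <- function(tree, tol = 1e-6, context = "tree") {
  h <- node_heights(tree)
  tips <- h[seq_len(ape::Ntip(tree))]
  spread <- diff(range(tips))
  depth <- max(tips)
  if (spread > tol * max(depth, 1)) {
    stop(context, " is not ultrametric: tip-height spread ",
         format(spread, digits = 6), " exceeds tolerance (tree depth ",
         format(depth, digits = 6), ")", call. = FALSE)
  }
  invisible(tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
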