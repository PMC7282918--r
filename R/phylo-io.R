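#' Read and validate a time-calibrated tree
#'
#' Reads a Newick file with [ape][ape::read.tree] and enforces the contract a
#' time tree must satisfy before comparative analysis: every branch has a
#' positive length, tip labels are unique, and the tree is ultrametric (all
#' root-to-tip path lengths equal within a relative tolerance), with branch
#' lengths interpreted as time (here, millions of years). Polytomies are
#' accepted and preserved.
#'
#' @param path Path to a Newick file (branch lengths required).
#' @param tol Relative ultrametricity tolerance (fraction of tree depth).
#' @return An [ape::phylo] tree.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' tr <- read_newick(tf)
#' ape::Ntip(tr)
#' @export
read_newick <- function(path, tol = 1e-6) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_timetree(tree, tol = tol)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object to validate in place.
#' @export
validate_timetree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  bad <- which(is.na(tree$edge.length))
  if (length(bad) > 0) {
    stop("missing branch length on edge(s) leading to node(s): ",
         paste(tree$edge[bad, 2], collapse = ", "), call. = FALSE)
  }
  nonpos <- which(tree$edge.length <= 0)
  if (length(nonpos) > 0) {
    stop("non-positive branch length on edge(s) leading to node(s): ",
         paste(tree$edge[nonpos, 2], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  check_ultrametric(tree, tol = tol)
  tree
}

#' Read a species-by-toxin relative expression table
#'
#' Reads a delimited text file whose first column holds species labels and
#' whose remaining columns hold relative-abundance values for one toxin
#' family each. Repeated species labels are kept as replicate transcriptomes
#' of that species. Missing cells (`NA` or empty) are recorded as 0 — in a
#' relative-composition table an undetected toxin has zero abundance.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param delim Field delimiter; if `NULL`, sniffed from the first line
#'   (tab if present, else comma).
#' @return A tibble with a `species` character column followed by one
#'   numeric column per toxin family.
#' @export
read_expression_table <- function(path, delim = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a species column plus at ",
                          "least one toxin column", call. = FALSE)
  names(raw)[1] <- "species"
  if (anyDuplicated(names(raw)[-1])) {
    stop("duplicated toxin labels in header", call. = FALSE)
  }
  out <- raw
  for (j in seq(2, ncol(raw))) {
    cell <- raw[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & toupper(cell) != "NA" &
                   is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric value '", cell[bad[1]], "' at row ", bad[1],
           ", column '", names(raw)[j], "'", call. = FALSE)
    }
    num[is.na(num)] <- 0
    if (any(num < 0)) {
      stop("negative abundance at row ", which(num < 0)[1], ", column '",
           names(raw)[j], "'", call. = FALSE)
    }
    out[[j]] <- num
  }
  validate_expression_table(out)
}

#' @rdname read_expression_table
#' @param table A data frame to validate as an expression table.
#' @export
validate_expression_table <- function(table) {
  if (!is.data.frame(table) || !"species" %in% names(table)) {
    stop("expression table must have a 'species' column", call. = FALSE)
  }
  vals <- as.matrix(table[setdiff(names(table), "species")])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("toxin columns must be finite numerics", call. = FALSE)
  }
  if (any(vals < 0)) stop("abundances must be non-negative", call. = FALSE)
  tibble::as_tibble(table)
}

#' Retain toxin families present in a minimum fraction of species
#'
#' A toxin counts as present in a species when any replicate transcriptome of
#' that species has abundance > 0. Toxin columns whose presence fraction
#' across species falls below `min_fraction` are dropped; column order is
#' preserved. This focuses the analysis on widely shared venom components,
#' for which phylogenetic inference is not dominated by absences.
#'
#' @param table Expression table (see [read_expression_table()]).
#' @param min_fraction Minimum fraction of species, in (0, 1]. Default 0.5.
#' @return The filtered expression table.
#' @export
presence_filter <- function(table, min_fraction = 0.5) {
  table <- validate_expression_table(table)
  stopifnot(min_fraction > 0, min_fraction <= 1)
  toxins <- setdiff(names(table), "species")
  pres <- vapply(toxins, function(tx) {
    by_sp <- tapply(table[[tx]] > 0, table$species, any)
    mean(by_sp)
  }, numeric(1))
  keep <- names(pres)[pres >= min_fraction]
  if (length(keep) == 0) {
    stop("no toxin passes the presence filter at min_fraction = ",
         min_fraction, "; per-toxin presence fractions: ",
         paste(sprintf("%s=%.3f", names(pres), pres), collapse = ", "),
         call. = FALSE)
  }
  table[c("species", keep)]
}

#' Scale one toxin's expression by the average within-species variance
#'
#' Species means are taken across replicate transcriptomes, then divided by a
#' scaling constant derived from the average within-species variance (sample
#' variance, n − 1 denominator, over species with at least two replicates).
#' By default the divisor is the square root of that average variance, so
#' values come out in within-species standard-deviation units — the usual
#' standardisation target. The alternative reading (divide by the variance
#' itself) is one flag away. If no species has replicates, or the average
#' within-species variance is zero, the constant falls back to 1 with a
#' warning and the species means pass through unchanged.
#'
#' @param table Expression table.
#' @param toxin Name of the toxin column to scale.
#' @param divisor `"sd"` (default) divides by the square root of the average
#'   within-species variance; `"variance"` divides by the variance itself.
#' @param transform Optional transform applied to abundances before scaling:
#'   `"none"` (default), `"log"`, or `"logit"`; the latter two require
#'   values in (0, 1) and (0, 1) respectively.
#' @return A `scaled_trait` tibble (`species`, `value`) carrying the toxin
#'   name and `scaling_constant` as attributes.
#' @export
scale_by_within_species_variance <- function(table, toxin,
                                             divisor = c("sd", "variance"),
                                             transform = c("none", "log",
                                                           "logit")) {
  table <- validate_expression_table(table)
  divisor <- match.arg(divisor)
  transform <- match.arg(transform)
  if (!toxin %in% names(table)) {
    stop("toxin '", toxin, "' not found in table", call. = FALSE)
  }
  x <- table[[toxin]]
  x <- switch(transform,
    none = x,
    log = {
      if (any(x <= 0)) stop("log transform requires positive abundances",
                            call. = FALSE)
      log(x)
    },
    logit = {
      if (any(x <= 0 | x >= 1)) stop("logit transform requires abundances ",
                                     "in (0, 1)", call. = FALSE)
      log(x / (1 - x))
    })
  sp <- table$species
  means <- tapply(x, sp, mean)
  nrep <- tapply(x, sp, length)
  wv <- tapply(x, sp, function(z) if (length(z) >= 2) stats::var(z) else NA)
  wv <- wv[!is.na(wv)]
  if (length(wv) == 0) {
    warning("no species has replicate transcriptomes; scaling constant ",
            "set to 1", call. = FALSE)
    const <- 1
  } else {
    avg <- mean(wv)
    if (avg <= 0) {
      warning("average within-species variance is zero; scaling constant ",
              "set to 1", call. = FALSE)
      const <- 1
    } else {
      const <- if (divisor == "sd") sqrt(avg) else avg
    }
  }
  # tapply orders by factor level; restore first-appearance species order
  ord <- unique(sp)
  new_scaled_trait(ord, as.numeric(means[ord]) / const, toxin = toxin,
                   scaling_constant = const)
}

#' Prune tree and trait to their shared species
#'
#' Drops tree tips without trait values and trait entries without tips, then
#' collapses any degree-2 internal nodes created by pruning (summing branch
#' lengths), so root-to-tip depth is unchanged.
#'
#' @param tree A time tree.
#' @param trait A `scaled_trait` tibble or named numeric vector.
#' @return A list with elements `tree` and `trait` restricted to the shared
#'   species.
#' @export
prune_to_overlap <- function(tree, trait) {
  x <- as_trait_vector(trait)
  shared <- intersect(tree$tip.label, names(x))
  if (length(shared) < 3) {
    stop("need at least 3 species shared between tree and trait; found ",
         length(shared), call. = FALSE)
  }
  tree2 <- if (length(shared) == ape::Ntip(tree)) tree else
    ape::keep.tip(tree, shared)
  x2 <- x[tree2$tip.label]
  list(tree = tree2,
       trait = new_scaled_trait(names(x2), unname(x2),
                                toxin = attr(trait, "toxin") %||% NA_character_,
                                scaling_constant =
                                  attr(trait, "scaling_constant") %||% NA_real_))
}

#' Write a scaled trait vector as two-column TSV
#'
#' @param trait A `scaled_trait` tibble.
#' @param path Output path.
#' @export
write_scaled_trait <- function(trait, path) {
  readr::write_tsv(tibble::as_tibble(trait)[c("species", "value")], path)
  invisible(path)
}
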