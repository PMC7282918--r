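#' Akaike weights and jump-class summary for a set of fits
#'
#' Computes per-model Akaike weights w_i = exp(-Delta_i / 2) /
#' sum_j exp(-Delta_j / 2) with Delta_i = AIC_i - min AIC, then summarises
#' at the class level: BM, OU and EB keep their own weights, while the
#' pulsed class is represented by the *maximum* weight among the jump
#' models present (the individual jump models rarely differ much in fit, so
#' the best one stands for the class).
#'
#' @param fits A `levy_fit_list` or list of `levy_fit` objects on the same
#'   data.
#' @param allow_nonconverged Refuse fits flagged non-converged unless set
#'   to `TRUE`.
#' @return A `model_comparison` object with tibbles `models` (per-model
#'   weights) and `classes` (class-level weights).
#' @examples
#' # weights from AIC values alone follow the closed-form formula:
#' # AICs {100, 102, 104} -> weights {0.665, 0.245, 0.090}
#' @export
aic_weights <- function(fits, allow_nonconverged = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 2)
  fits <- unclass(fits)
  ok <- vapply(fits, function(f) inherits(f, "levy_fit"), logical(1))
  if (!all(ok)) stop("fits must be levy_fit objects", call. = FALSE)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) {
    stop("fits were not computed on identical data (tip counts differ)",
         call. = FALSE)
  }
  bad <- vapply(fits, function(f) !f$converged, logical(1))
  if (any(bad) && !allow_nonconverged) {
    stop("non-converged fit(s): ",
         paste(vapply(fits[bad], function(f) f$model, character(1)),
               collapse = ", "),
         "; refit or pass allow_nonconverged = TRUE", call. = FALSE)
  }
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  if (any(!is.finite(aic))) stop("non-finite AIC", call. = FALSE)
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  models <- tibble::tibble(
    model = vapply(fits, function(f) f$model, character(1)),
    class = vapply(fits, function(f) f$class, character(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    AIC = aic, delta = delta, weight = w)
  cls <- list()
  for (g in c("BM", "OU", "EB")) {
    if (g %in% models$model) {
      cls[[g]] <- tibble::tibble(class = g,
                                 weight = models$weight[models$model == g],
                                 representative = g)
    }
  }
  jm <- models[models$class == "pulsed", , drop = FALSE]
  if (nrow(jm) > 0) {
    i <- which.max(jm$weight)
    cls[["pulsed"]] <- tibble::tibble(class = "pulsed",
                                      weight = jm$weight[i],
                                      representative = jm$model[i])
  }
  structure(list(models = models, classes = dplyr::bind_rows(cls)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$models)
  cat("class summary (pulsed = max over jump-model weights):\n")
  print(x$classes)
  cat("selected:", select_best(x), "\n")
  invisible(x)
}

#' Select the best-supported model class
#'
#' A class is favoured only if its weight is at least `factor` times the
#' weight of every competing class; otherwise the comparison is declared
#' `"inconclusive"`. The default two-fold rule is deliberately blunt: it
#' removes ambiguity when many similarly-supported models are compared.
#'
#' @param x A `model_comparison` or a data frame with columns `class` and
#'   `weight`.
#' @param factor Required weight ratio (default 2).
#' @return The selected class name, or `"inconclusive"`.
#' @export
select_best <- function(x, factor = 2) {
  tbl <- if (inherits(x, "model_comparison")) x$classes else
    tibble::as_tibble(x)
  stopifnot(all(c("class", "weight") %in% names(tbl)))
  w <- stats::setNames(tbl$weight, tbl$class)
  i <- which.max(w)
  if (length(w) == 1 || w[i] >= factor * max(w[-i])) names(w)[i] else
    "inconclusive"
}

#' Fit all models and compare them by Akaike weight
#'
#' One-call wrapper: [fit_all_models()], then [aic_weights()]; the fits are
#' attached to the result as attribute `"fits"`.
#'
#' @inheritParams fit_all_models
#' @inheritParams aic_weights
#' @return A `model_comparison` object.
#' @export
compare_models <- function(tree, trait, models = levy_models(),
                           restarts = 10, grid_size = 1024, seed = NULL,
                           allow_nonconverged = FALSE) {
  fits <- fit_all_models(tree, trait, models = models, restarts = restarts,
                         grid_size = grid_size, seed = seed)
  cmp <- aic_weights(fits, allow_nonconverged = allow_nonconverged)
  attr(cmp, "fits") <- fits
  cmp
}
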