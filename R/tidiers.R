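# broom-style methods ---------------------------------------------------

#' @export
tidy.levy_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(unlist(x$params)))
}

#' @export
glance.levy_fit <- function(x, ...) {
  tibble::tibble(model = x$model, class = x$class, logLik = x$loglik,
                 AIC = x$aic, k = x$k, converged = x$converged,
                 n = x$n)
}

#' @export
tidy.model_comparison <- function(x, ...) x$models

#' @export
glance.model_comparison <- function(x, factor = 2, ...) {
  out <- tidyr::pivot_wider(x$classes[c("class", "weight")],
                            names_from = "class", values_from = "weight")
  out$selected <- select_best(x, factor = factor)
  out
}

#' @export
tidy.rateshift_sample <- function(x, ...) x$samples

#' @export
glance.rateshift_sample <- function(x, burnin = 0.1, ...) {
  kept <- retain_samples(x, burnin)
  tibble::tibble(
    n_samples = nrow(x$samples),
    generations = x$settings$ngenerations,
    thin = x$settings$thin,
    mean_nshifts = mean(kept$samples$nshifts),
    posterior_p0 = mean(kept$samples$nshifts == 0),
    ess_loglik = as.numeric(ess(x$samples$loglik)),
    ess_nshifts = as.numeric(ess(x$samples$nshifts)))
}

#' @export
tidy.shift_configuration <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(edge = NA_integer_, time = 0, beta = x$root_beta,
                   b = x$root_b, regime = "root"),
    if (nrow(x$events) > 0) dplyr::mutate(x$events, regime = "shift"))
}

#' @export
tidy.bayes_factor_result <- function(x, ...) x$posterior

#' @export
glance.bayes_factor_result <- function(x, ...) {
  tibble::tibble(bf = x$bf, is_bound = x$is_bound,
                 posterior_p0 = x$posterior_p0, prior_p0 = x$prior_p0,
                 n_samples = x$n_samples)
}
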