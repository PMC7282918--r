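# ggplot2 methods --------------------------------------------------------

#' Plot a rate-through-time curve
#'
#' Posterior mean rate with its credible band, time running from the root
#' (left) to the present (right).
#'
#' @param object A `rate_through_time` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_through_time <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_before_present,
                               y = .data$rate_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate_lower,
                                      ymax = .data$rate_upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "time before present (My)",
                  y = expression(paste("evolutionary rate (",
                                       trait^2, " / My)"))) +
    ggplot2::theme_minimal()
}

#' Plot class-level Akaike weights
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$classes,
                  ggplot2::aes(x = .data$class, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Akaike weight",
                  subtitle = paste("selected:", select_best(object))) +
    ggplot2::theme_minimal()
}

#' Trace plots for a rate-shift MCMC run
#'
#' Log-likelihood and shift-count traces of the thinned chain, the visual
#' convergence check usually paired with the ESS numbers.
#'
#' @param object A `rateshift_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rateshift_sample <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$samples[c("sample", "loglik", "nshifts")],
    cols = c("loglik", "nshifts"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "thinned sample", y = NULL) +
    ggplot2::theme_minimal()
}
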