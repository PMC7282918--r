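# model registry ------------------------------------------------------------

# free parameters per model (sigma_tip always free; root state is profiled
# out by REML and the OU optimum is not separately identifiable from it, so
# neither is counted)
.levy_model_params <- list(
  BM    = c("sigma2", "sigma_tip"),
  OU    = c("sigma2", "alpha", "sigma_tip"),
  EB    = c("sigma2", "r", "sigma_tip"),
  JN    = c("lambda", "delta", "sigma_tip"),
  NIG   = c("alpha_nig", "delta_nig", "sigma_tip"),
  BMJN  = c("sigma2", "lambda", "delta", "sigma_tip"),
  BMNIG = c("sigma2", "alpha_nig", "delta_nig", "sigma_tip"),
  EBJN  = c("r", "lambda", "delta", "sigma_tip"),
  EBNIG = c("r", "alpha_nig", "delta_nig", "sigma_tip")
)

#' Names of the supported trait-evolution models
#'
#' Three Gaussian incremental models (BM, OU, EB) and six pulsed
#' (Levy-process) models: pure-jump JN and NIG, their Brownian compounds
#' BMJN and BMNIG, and their early-burst time-rescaled variants EBJN and
#' EBNIG.
#' @return Character vector of model names.
#' @export
levy_models <- function() names(.levy_model_params)

model_class <- function(model) {
  if (model %in% c("BM", "OU", "EB")) model else "pulsed"
}

jump_models <- function() setdiff(levy_models(), c("BM", "OU", "EB"))

is_eb_variant <- function(model) model %in% c("EB", "EBJN", "EBNIG")

jump_type_code <- function(model) {
  switch(model,
         BM = 0L, OU = 0L, EB = 0L,
         JN = 1L, BMJN = 1L, EBJN = 1L,
         NIG = 2L, BMNIG = 2L, EBNIG = 2L,
         stop("unknown model '", model, "'", call. = FALSE))
}

#' Specify a trait-evolution model with its parameters
#'
#' Builds a validated parameter set for one of the nine models returned by
#' [levy_models()] (plus `"SHIFTED_BM"` accepted for simulation via
#' [simulate_shifted_bm()]). Parameters and units:
#' * `sigma2` — Brownian rate (trait^2 / My)
#' * `alpha` — OU pull towards the optimum (1 / My); `theta` — optimum
#'   (trait units, default equal to the root state)
#' * `r` — early-burst exponent (1 / My, must be <= 0)
#' * `lambda` — jump intensity (events / My); `delta` — jump-size SD
#'   (trait units) for compound-Poisson (JN-type) jumps
#' * `alpha_nig` — NIG tail-heaviness; `delta_nig` — NIG scale per unit
#'   time (symmetric, centred parameterisation)
#' * `sigma_tip` — Gaussian tip-noise SD (trait units)
#' * `mu` — directional drift (trait / My); retained for simulation but
#'   fixed at 0 in all fits (REML on an ultrametric tree cannot separate
#'   drift from the root state)
#'
#' @param model Model name.
#' @param sigma2,alpha,theta,r,lambda,delta,alpha_nig,delta_nig Parameters,
#'   see above. Only the fields belonging to `model` are required; for the
#'   pure-jump models `sigma2` may be supplied for simulation (defaults 0).
#' @param sigma_tip Tip-noise SD, >= 0.
#' @param mu Drift, default 0.
#' @return An object of class `levy_model_spec`.
#' @export
levy_model_spec <- function(model, sigma2 = NULL, alpha = NULL, theta = 0,
                            r = NULL, lambda = NULL, delta = NULL,
                            alpha_nig = NULL, delta_nig = NULL,
                            sigma_tip = 0, mu = 0) {
  if (!model %in% levy_models()) {
    stop("unknown model '", model, "'; see levy_models()", call. = FALSE)
  }
  need <- setdiff(.levy_model_params[[model]], "sigma_tip")
  supplied <- list(sigma2 = sigma2, alpha = alpha, r = r, lambda = lambda,
                   delta = delta, alpha_nig = alpha_nig,
                   delta_nig = delta_nig)
  for (p in need) {
    if (is.null(supplied[[p]])) {
      stop("model ", model, " requires parameter '", p, "'", call. = FALSE)
    }
  }
  pos <- c("sigma2", "alpha", "lambda", "delta", "alpha_nig", "delta_nig")
  for (p in pos) {
    v <- supplied[[p]]
    if (!is.null(v) && (!is.finite(v) || v < 0)) {
      stop("parameter '", p, "' must be finite and >= 0", call. = FALSE)
    }
  }
  if (!is.null(r) && r > 0) {
    stop("early-burst exponent r must be <= 0", call. = FALSE)
  }
  if (!is.finite(sigma_tip) || sigma_tip < 0) {
    stop("sigma_tip must be finite and >= 0", call. = FALSE)
  }
  structure(list(model = model,
                 sigma2 = sigma2 %||% 0,
                 alpha = alpha %||% 0,
                 theta = theta,
                 r = r %||% 0,
                 lambda = lambda %||% 0,
                 delta = delta %||% 0,
                 alpha_nig = alpha_nig %||% 0,
                 delta_nig = delta_nig %||% 0,
                 sigma_tip = sigma_tip,
                 mu = mu),
            class = "levy_model_spec")
}

#' @export
print.levy_model_spec <- function(x, ...) {
  cat("<levy_model_spec> ", x$model, " (class ", model_class(x$model), ")\n",
      sep = "")
  pars <- .levy_model_params[[x$model]]
  for (p in pars) cat("  ", p, " = ", format(x[[p]], digits = 6), "\n",
                      sep = "")
  invisible(x)
}

#' Characteristic exponent of a time-homogeneous Levy model
#'
#' Returns psi(k) in the Levy-Khinchine representation, so the increment of
#' the process over a branch of length t has characteristic function
#' exp(t * psi(k)). Components: drift i*mu*k; Brownian −sigma2 k^2 / 2;
#' JN-type compound-Poisson jumps lambda (exp(−delta^2 k^2 / 2) − 1);
#' symmetric NIG delta_nig (alpha_nig − sqrt(alpha_nig^2 + k^2)). EB
#' variants are time-inhomogeneous and are handled by branch rescaling, not
#' by a homogeneous exponent; OU is likewise excluded.
#'
#' @param spec A [levy_model_spec()] for BM, JN, NIG, BMJN or BMNIG.
#' @param k Frequency (numeric vector).
#' @return Complex vector psi(k).
#' @export
levy_char_exponent <- function(spec, k) {
  stopifnot(inherits(spec, "levy_model_spec"))
  if (is_eb_variant(spec$model) || spec$model == "OU") {
    stop("model ", spec$model, " is not a time-homogeneous Levy process; ",
         "its likelihood is obtained by branch rescaling", call. = FALSE)
  }
  psi <- complex(real = -0.5 * spec$sigma2 * k^2, imaginary = spec$mu * k)
  jt <- jump_type_code(spec$model)
  if (jt == 1L) {
    psi <- psi + spec$lambda * (exp(-0.5 * spec$delta^2 * k^2) - 1)
  } else if (jt == 2L) {
    psi <- psi + spec$delta_nig *
      (spec$alpha_nig - sqrt(spec$alpha_nig^2 + k^2))
  }
  psi
}

# stationary increment variance per unit time (used for initial values and
# simulation checks); EB variants: per unit *rescaled* time
increment_variance_rate <- function(spec) {
  v <- spec$sigma2
  jt <- jump_type_code(spec$model)
  if (jt == 1L) v <- v + spec$lambda * spec$delta^2
  if (jt == 2L) v <- v + if (spec$alpha_nig > 0)
    spec$delta_nig / spec$alpha_nig else 0
  v
}
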