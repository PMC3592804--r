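#' Model specification for the fractional-polynomial PK mixed model
#'
#' The population curve on the log-concentration scale is
#' \deqn{\log c(t) = \beta_0 + \beta_1 t^{p_1} + \beta_2 t^{p_2} + b_i,}
#' with default powers \eqn{(p_1, p_2) = (1, -1)}, i.e.
#' \eqn{\beta_0 + \beta_1 t + \beta_2 / t}. With \eqn{\beta_1 < 0} and
#' \eqn{\beta_2 < 0} this gives an increasing absorption phase followed by a
#' decreasing elimination phase, mirroring the one-compartment model.
#' Residual errors are either isotropic multivariate Student t (per-subject
#' blocks, scatter \eqn{\sigma_2 I}, `nu` degrees of freedom), isotropic
#' normal, or — for AIC comparison only — gamma with log link on the raw
#' concentration scale.
#'
#' For the t family `sigma2` is the scatter-matrix element, not the error
#' variance; the implied marginal variance is `sigma2 * nu / (nu - 2)`.
#'
#' @param error_family One of `"t"`, `"normal"`, `"gamma"`.
#' @param powers Length-2 numeric vector of distinct fractional-polynomial
#'   exponents; default `c(1, -1)`.
#' @param nu Degrees of freedom (> 2) for the t family; ignored otherwise.
#' @param dose_offset If `TRUE`, add `log(dose)` as a fixed-coefficient
#'   offset to the linear predictor. Defaults to `FALSE` (common-dose
#'   designs absorb the dose into the intercept).
#' @param gamma_shape Positive shape parameter, required by the likelihood
#'   when `error_family = "gamma"` (usually profiled; see
#'   [fit_and_compare()]).
#' @return An object of class `pk_model_spec`.
#' @export
#' @examples
#' pk_model_spec("t", nu = 4)
#' pk_model_spec("normal")
pk_model_spec <- function(error_family = c("t", "normal", "gamma"),
                          powers = c(1, -1), nu = 4,
                          dose_offset = FALSE, gamma_shape = NULL) {
  error_family <- match.arg(error_family)
  powers <- as.numeric(powers)
  if (length(powers) != 2L || any(!is.finite(powers)))
    stop("powers must be two finite exponents")
  if (powers[1] == powers[2])
    stop("the two fractional-polynomial powers must differ")
  if (error_family == "t") {
    if (is.null(nu) || !is.finite(nu) || nu <= 2)
      stop("the t family needs degrees of freedom nu > 2")
  }
  if (!is.null(gamma_shape) && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("gamma_shape must be positive")
  structure(
    list(error_family = error_family, powers = powers,
         nu = if (error_family == "t") as.numeric(nu) else NULL,
         dose_offset = isTRUE(dose_offset),
         gamma_shape = gamma_shape),
    class = "pk_model_spec"
  )
}

#' @export
print.pk_model_spec <- function(x, ...) {
  cat("pk_model_spec:", x$error_family, "errors")
  if (x$error_family == "t") cat(" (nu =", x$nu, ")")
  cat("; powers (", x$powers[1], ",", x$powers[2], ")",
      if (x$dose_offset) "; log-dose offset" else "", "\n", sep = "")
  invisible(x)
}

#' Parameter state of the hierarchical model
#'
#' Holds the fixed effects `beta = (beta0, beta1, beta2)`, one scalar random
#' intercept per subject, the random-effect variance `sigma1` and the
#' residual scatter `sigma2`. The one-compartment sign constraints
#' `beta1 < 0`, `beta2 < 0` and positivity of both variance components are
#' enforced at construction; the sampler enforces them by rejection.
#'
#' @param beta Numeric triple (intercept, coefficient on `t^p1`,
#'   coefficient on `t^p2`).
#' @param b Numeric vector of subject random intercepts.
#' @param sigma1 Random-effect variance (> 0).
#' @param sigma2 Residual scatter element (> 0).
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(beta, b, sigma1, sigma2) {
  beta <- as.numeric(beta)
  if (length(beta) != 3L || any(!is.finite(beta)))
    stop("beta must be a finite numeric triple")
  if (beta[2] >= 0 || beta[3] >= 0)
    stop("constraints violated: beta1 and beta2 must be negative ",
         "(increasing absorption, decreasing elimination)")
  b <- as.numeric(b)
  if (any(!is.finite(b))) stop("random effects b must be finite")
  if (!is.finite(sigma1) || sigma1 <= 0) stop("sigma1 must be > 0")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  structure(list(beta = beta, b = b,
                 sigma1 = as.numeric(sigma1), sigma2 = as.numeric(sigma2)),
            class = "parameter_state")
}

#' Prior specification
#'
#' Independent normal priors on the three fixed effects (diagonal prior
#' covariance) and gamma priors on the two variance components. The prior
#' mean of `beta` is conventionally set to an initial estimate; gradient
#' components default to small negative values consistent with the sign
#' constraints. Variance-component priors default to diffuse
#' gamma(0.01, rate 0.01); set `family = "invgamma"` for the inverse-gamma
#' convention.
#'
#' @param beta_mean Prior mean triple for the fixed effects.
#' @param beta_var Prior variance triple (diagonal covariance).
#' @param sigma1_shape,sigma1_rate Gamma prior parameters for `sigma1`.
#' @param sigma2_shape,sigma2_rate Gamma prior parameters for `sigma2`.
#' @param family Prior family for the variance components: `"gamma"`
#'   (default) or `"invgamma"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_mean = c(0.1, -0.1, -0.1),
                       beta_var = c(100, 100, 100),
                       sigma1_shape = 0.01, sigma1_rate = 0.01,
                       sigma2_shape = 0.01, sigma2_rate = 0.01,
                       family = c("gamma", "invgamma")) {
  family <- match.arg(family)
  beta_mean <- as.numeric(beta_mean); beta_var <- as.numeric(beta_var)
  stopifnot(length(beta_mean) == 3L, length(beta_var) == 3L)
  if (any(beta_var <= 0)) stop("prior variances must be positive")
  for (v in c(sigma1_shape, sigma1_rate, sigma2_shape, sigma2_rate))
    if (!is.finite(v) || v <= 0) stop("gamma prior parameters must be positive")
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 sigma1_shape = sigma1_shape, sigma1_rate = sigma1_rate,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
                 family = family),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Iteration counts follow the usual single-chain protocol: `n_iter` sweeps,
#' the first `burn_in` discarded, posterior summaries taken from the last
#' `summary_window` retained iterations. Proposal standard deviations are
#' per parameter block and, when `adapt = TRUE`, are tuned during burn-in
#' toward a 25--45% acceptance rate and frozen afterwards.
#'
#' @param n_iter Total sweeps (default 5000).
#' @param burn_in Discarded initial sweeps (default 4000; must be < `n_iter`).
#' @param summary_window Iterations summarized from the end of the chain
#'   (default 1000; at most `n_iter - burn_in`).
#' @param proposal_scales Named list with elements `beta` (length 3),
#'   `sigma1`, `sigma2`, `b`, and `shift` (the joint location-shift move of
#'   [run_chain()]); `NULL` for defaults.
#' @param seed Integer seed for reproducible chains; `NULL` leaves the RNG
#'   state alone.
#' @param adapt Tune proposal scales during burn-in?
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000, burn_in = 4000,
                        summary_window = min(1000, n_iter - burn_in),
                        proposal_scales = NULL, seed = NULL, adapt = TRUE) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  summary_window <- as.integer(summary_window)
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  if (summary_window < 1 || summary_window > n_iter - burn_in)
    stop("summary_window must lie in [1, n_iter - burn_in]")
  # sigma scales are on the log scale (multiplicative proposals)
  scales <- list(beta = c(0.05, 0.01, 0.05), sigma1 = 0.8,
                 sigma2 = 0.4, b = 0.05, shift = 0.05)
  if (!is.null(proposal_scales)) {
    for (nm in names(proposal_scales)) {
      if (!nm %in% names(scales)) stop("unknown proposal scale block: ", nm)
      scales[[nm]] <- as.numeric(proposal_scales[[nm]])
    }
    if (length(scales$beta) == 1L) scales$beta <- rep(scales$beta, 3L)
    stopifnot(length(scales$beta) == 3L)
  }
  if (any(unlist(scales) < 0)) stop("proposal scales must be non-negative")
  structure(list(n_iter = n_iter, burn_in = burn_in,
                 summary_window = summary_window,
                 proposal_scales = scales,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 adapt = isTRUE(adapt)),
            class = "mcmc_config")
}
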