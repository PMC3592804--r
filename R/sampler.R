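#' Log prior density
#'
#' Independent normal priors on the fixed effects, gamma (or inverse-gamma)
#' priors on the variance components, plus the second-stage normal density
#' of the subject random intercepts given `sigma1`.
#'
#' @param state A [parameter_state()].
#' @param priors A [prior_spec()].
#' @return Scalar log-density.
#' @export
log_prior <- function(state, priors) {
  stopifnot(inherits(state, "parameter_state"), inherits(priors, "prior_spec"))
  sum(stats::dnorm(state$beta, priors$beta_mean, sqrt(priors$beta_var),
                   log = TRUE)) +
    var_prior_logpdf(state$sigma1, priors$sigma1_shape, priors$sigma1_rate,
                     priors$family) +
    var_prior_logpdf(state$sigma2, priors$sigma2_shape, priors$sigma2_rate,
                     priors$family) +
    sum(stats::dnorm(state$b, 0, sqrt(state$sigma1), log = TRUE))
}

var_prior_logpdf <- function(x, shape, rate, family = "gamma") {
  if (family == "gamma") {
    stats::dgamma(x, shape = shape, rate = rate, log = TRUE)
  } else {
    shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
  }
}

#' Unnormalized log posterior
#'
#' `conditional_loglik(data, state, spec) + log_prior(state, priors)`.
#'
#' @inheritParams log_prior
#' @param data A [pk_dataset()].
#' @param spec A [pk_model_spec()].
#' @return Scalar unnormalized log posterior.
#' @export
log_posterior <- function(state, data, spec, priors) {
  conditional_loglik(data, state, spec) + log_prior(state, priors)
}

# does a proposed state satisfy the one-compartment constraints?
state_is_valid <- function(beta, sigma1, sigma2) {
  beta[2] < 0 && beta[3] < 0 && sigma1 > 0 && sigma2 > 0
}

#' Single Metropolis-Hastings rejection step
#'
#' Reference implementation of one constrained update of a parameter
#' block. Fixed effects and random intercepts use a symmetric Gaussian
#' random walk; a proposal violating the one-compartment constraints
#' (`beta1 < 0`, `beta2 < 0`, `sigma1 > 0`, `sigma2 > 0`) is rejected
#' outright, and otherwise accepted with probability `min(1, p)` where
#' `p = exp(log_posterior(proposed) - log_posterior(current))`. Variance
#' components use a Gaussian random walk on the log scale (which respects
#' positivity by construction), with the corresponding Hastings correction.
#' [run_chain()] applies the same rules with cached likelihood pieces.
#'
#' @param state Current [parameter_state()].
#' @param block One of `"beta0"`, `"beta1"`, `"beta2"`, `"sigma1"`,
#'   `"sigma2"`, or `"b<i>"` for the i-th subject's random intercept.
#' @param data,spec,priors Model ingredients as in [log_posterior()].
#' @param config An [mcmc_config()] supplying the proposal scale for the
#'   block (a scale of 0 proposes the current value, which is always
#'   accepted).
#' @return A list with elements `state` (the new [parameter_state()]) and
#'   `accepted` (logical).
#' @export
mh_step <- function(state, block, data, spec, priors, config = mcmc_config()) {
  stopifnot(inherits(state, "parameter_state"))
  sc <- config$proposal_scales
  prop <- state
  hastings <- 0  # non-zero for the multiplicative variance proposals
  if (block %in% c("beta0", "beta1", "beta2")) {
    k <- match(block, c("beta0", "beta1", "beta2"))
    prop$beta[k] <- state$beta[k] + stats::rnorm(1, 0, sc$beta[k])
  } else if (block == "sigma1") {
    prop$sigma1 <- state$sigma1 * exp(stats::rnorm(1, 0, sc$sigma1))
    hastings <- log(prop$sigma1 / state$sigma1)
  } else if (block == "sigma2") {
    prop$sigma2 <- state$sigma2 * exp(stats::rnorm(1, 0, sc$sigma2))
    hastings <- log(prop$sigma2 / state$sigma2)
  } else if (grepl("^b[0-9]+$", block)) {
    i <- as.integer(sub("^b", "", block))
    if (i < 1 || i > length(state$b)) stop("no such random-effect block: ", block)
    prop$b[i] <- state$b[i] + stats::rnorm(1, 0, sc$b)
  } else {
    stop("unknown parameter block: ", block)
  }
  if (!state_is_valid(prop$beta, prop$sigma1, prop$sigma2))
    return(list(state = state, accepted = FALSE))
  dlp <- log_posterior(prop, data, spec, priors) -
    log_posterior(state, data, spec, priors) + hastings
  if (log(stats::runif(1)) < dlp) {
    list(state = prop, accepted = TRUE)
  } else {
    list(state = state, accepted = FALSE)
  }
}

#' Run the constrained Metropolis-Hastings sampler
#'
#' Sweeps the parameter blocks — each fixed-effect component, `sigma1`,
#' `sigma2`, then every subject random intercept — with symmetric Gaussian
#' random-walk proposals and the constrained acceptance rule of
#' [mh_step()]. Random intercepts are updated element-wise in a single
#' vectorized pass (their full conditionals are mutually independent given
#' the other blocks). Each sweep ends with a joint location-shift move
#' (`beta0 + d`, all `b_i - d`) that travels along the intercept/random-
#' effect ridge; the likelihood is invariant under it, so it accepts on the
#' prior ratio alone and greatly improves `beta0` mixing.
#' With `config$adapt = TRUE` proposal scales are tuned
#' in batches of 50 iterations during burn-in toward a 25--45% acceptance
#' rate and frozen afterwards, so the retained chain is a valid MH sample.
#'
#' @param data A [pk_dataset()].
#' @param spec A [pk_model_spec()] with `"t"` or `"normal"` family (the
#'   gamma family enters only the AIC comparison; see [fit_and_compare()]).
#' @param priors A [prior_spec()].
#' @param config An [mcmc_config()]; `config$seed` makes the chain
#'   bit-reproducible.
#' @param init Optional named list overriding the initial values
#'   `beta = c(0.1, -0.1, -0.1)`, `b = 0`, `sigma1 = sigma2 = 0.01`.
#' @return A `ppk_chain` object: `draws` (n_iter x (5 + m) matrix, columns
#'   `beta0, beta1, beta2, sigma1, sigma2, b_<id>`), `burn_in`,
#'   `summary_window`, `accept_rates` (post-burn-in, per block),
#'   `proposal_scales` (final), `spec`, `config`, `subject_ids`.
#' @export
#' @examples
#' sim <- simulate_dataset(preset_example(1, seed = 1))
#' fit <- run_chain(sim$data, pk_model_spec("t", nu = 4),
#'                  config = mcmc_config(n_iter = 300, burn_in = 200,
#'                                       summary_window = 100, seed = 1))
#' summarize_chain(fit)
run_chain <- function(data, spec, priors = prior_spec(),
                      config = mcmc_config(), init = NULL) {
  stopifnot(inherits(data, "pk_dataset"), inherits(spec, "pk_model_spec"),
            inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  if (spec$error_family == "gamma")
    stop("the sampler supports the t and normal families; ",
         "the gamma family is used only for AIC comparison")
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- stack_dataset(data, spec)
  m <- st$m

  beta <- c(0.1, -0.1, -0.1); b <- rep(0, m); s1 <- 0.01; s2 <- 0.01
  if (!is.null(init)) {
    # exact indexing: $ would partially match "b" against "beta"
    if (!is.null(init[["beta"]])) beta <- as.numeric(init[["beta"]])
    if (!is.null(init[["b"]])) b <- rep_len(as.numeric(init[["b"]]), m)
    if (!is.null(init[["sigma1"]])) s1 <- init[["sigma1"]]
    if (!is.null(init[["sigma2"]])) s2 <- init[["sigma2"]]
  }
  parameter_state(beta, b, s1, s2)  # validates constraints

  fam <- spec$error_family; nu <- spec$nu
  n_i <- st$n_i; grp <- st$grp; X <- st$X; y <- st$y_log
  mu <- drop(X %*% beta) + b[grp] + st$offset
  r <- y - mu
  ss <- drop(rowsum(r^2, grp, reorder = FALSE))
  ll <- family_loglik_ss(ss, n_i, s2, fam, nu)
  lp_beta <- stats::dnorm(beta, priors$beta_mean, sqrt(priors$beta_var),
                          log = TRUE)
  lp_s1 <- var_prior_logpdf(s1, priors$sigma1_shape, priors$sigma1_rate,
                            priors$family)
  lp_s2 <- var_prior_logpdf(s2, priors$sigma2_shape, priors$sigma2_rate,
                            priors$family)
  lp_b <- stats::dnorm(b, 0, sqrt(s1), log = TRUE)
  if (!is.finite(sum(ll) + sum(lp_beta) + lp_s1 + lp_s2 + sum(lp_b)))
    stop("log posterior is not finite at the initial values; ",
         "supply better init (e.g. a rough least-squares estimate)")

  sc <- config$proposal_scales
  sc_beta <- sc$beta; sc_s1 <- sc$sigma1; sc_s2 <- sc$sigma2; sc_b <- sc$b
  sc_shift <- sc$shift
  n_iter <- config$n_iter; burn_in <- config$burn_in
  draws <- matrix(NA_real_, n_iter, 5L + m)
  colnames(draws) <- c("beta0", "beta1", "beta2", "sigma1", "sigma2",
                       paste0("b_", st$ids))
  blocks <- c("beta0", "beta1", "beta2", "sigma1", "sigma2", "b", "shift")
  acc_batch <- stats::setNames(numeric(7), blocks)
  try_batch <- stats::setNames(numeric(7), blocks)
  acc_post <- stats::setNames(numeric(7), blocks)
  try_post <- stats::setNames(numeric(7), blocks)
  batch_len <- 50L

  for (iter in seq_len(n_iter)) {
    in_burn <- iter <= burn_in
    # fixed effects, component-wise
    for (k in 1:3) {
      prop <- beta[k] + stats::rnorm(1, 0, sc_beta[k])
      try_batch[k] <- try_batch[k] + 1; if (!in_burn) try_post[k] <- try_post[k] + 1
      if (k > 1 && prop >= 0) next  # constraint rejection
      r_new <- r - (prop - beta[k]) * X[, k]
      ss_new <- drop(rowsum(r_new^2, grp, reorder = FALSE))
      ll_new <- family_loglik_ss(ss_new, n_i, s2, fam, nu)
      lp_new <- stats::dnorm(prop, priors$beta_mean[k],
                             sqrt(priors$beta_var[k]), log = TRUE)
      if (log(stats::runif(1)) < sum(ll_new) - sum(ll) + lp_new - lp_beta[k]) {
        beta[k] <- prop; r <- r_new; ss <- ss_new; ll <- ll_new
        lp_beta[k] <- lp_new
        acc_batch[k] <- acc_batch[k] + 1; if (!in_burn) acc_post[k] <- acc_post[k] + 1
      }
    }
    # random-effect variance (likelihood does not involve sigma1 given b);
    # multiplicative (log-scale) random walk, Jacobian log(prop/s1)
    prop <- s1 * exp(stats::rnorm(1, 0, sc_s1))
    try_batch[4] <- try_batch[4] + 1; if (!in_burn) try_post[4] <- try_post[4] + 1
    {
      lp_s1_new <- var_prior_logpdf(prop, priors$sigma1_shape,
                                    priors$sigma1_rate, priors$family)
      lp_b_new <- stats::dnorm(b, 0, sqrt(prop), log = TRUE)
      if (log(stats::runif(1)) <
          lp_s1_new - lp_s1 + sum(lp_b_new) - sum(lp_b) + log(prop / s1)) {
        s1 <- prop; lp_s1 <- lp_s1_new; lp_b <- lp_b_new
        acc_batch[4] <- acc_batch[4] + 1; if (!in_burn) acc_post[4] <- acc_post[4] + 1
      }
    }
    # residual scatter, same multiplicative proposal
    prop <- s2 * exp(stats::rnorm(1, 0, sc_s2))
    try_batch[5] <- try_batch[5] + 1; if (!in_burn) try_post[5] <- try_post[5] + 1
    {
      ll_new <- family_loglik_ss(ss, n_i, prop, fam, nu)
      lp_s2_new <- var_prior_logpdf(prop, priors$sigma2_shape,
                                    priors$sigma2_rate, priors$family)
      if (log(stats::runif(1)) <
          sum(ll_new) - sum(ll) + lp_s2_new - lp_s2 + log(prop / s2)) {
        s2 <- prop; ll <- ll_new; lp_s2 <- lp_s2_new
        acc_batch[5] <- acc_batch[5] + 1; if (!in_burn) acc_post[5] <- acc_post[5] + 1
      }
    }
    # subject random intercepts: independent blocks, one vectorized pass
    b_prop <- b + stats::rnorm(m, 0, sc_b)
    r_new <- r - (b_prop - b)[grp]
    ss_new <- drop(rowsum(r_new^2, grp, reorder = FALSE))
    ll_new <- family_loglik_ss(ss_new, n_i, s2, fam, nu)
    lp_b_new <- stats::dnorm(b_prop, 0, sqrt(s1), log = TRUE)
    acc <- log(stats::runif(m)) < ll_new - ll + lp_b_new - lp_b
    try_batch[6] <- try_batch[6] + m; if (!in_burn) try_post[6] <- try_post[6] + m
    if (any(acc)) {
      keep <- acc[grp]
      r[keep] <- r_new[keep]
      b[acc] <- b_prop[acc]; ss[acc] <- ss_new[acc]
      ll[acc] <- ll_new[acc]; lp_b[acc] <- lp_b_new[acc]
      acc_batch[6] <- acc_batch[6] + sum(acc)
      if (!in_burn) acc_post[6] <- acc_post[6] + sum(acc)
    }

    # location-shift move along the beta0/b ridge: beta0 + d, b - d leaves
    # the likelihood invariant, so acceptance depends only on the priors;
    # decisive for beta0 mixing in random-intercept models
    d <- stats::rnorm(1, 0, sc_shift)
    try_batch[7] <- try_batch[7] + 1; if (!in_burn) try_post[7] <- try_post[7] + 1
    lp0_new <- stats::dnorm(beta[1] + d, priors$beta_mean[1],
                            sqrt(priors$beta_var[1]), log = TRUE)
    lp_b_new <- stats::dnorm(b - d, 0, sqrt(s1), log = TRUE)
    if (log(stats::runif(1)) <
        lp0_new - lp_beta[1] + sum(lp_b_new) - sum(lp_b)) {
      beta[1] <- beta[1] + d; b <- b - d
      lp_beta[1] <- lp0_new; lp_b <- lp_b_new
      acc_batch[7] <- acc_batch[7] + 1; if (!in_burn) acc_post[7] <- acc_post[7] + 1
    }

    draws[iter, ] <- c(beta, s1, s2, b)

    if (config$adapt && in_burn && iter %% batch_len == 0L) {
      rate <- acc_batch / pmax(try_batch, 1)
      fac <- ifelse(rate < 0.25, 0.7, ifelse(rate > 0.45, 1.4, 1))
      sc_beta <- pmax(sc_beta * fac[1:3], 1e-8)
      sc_s1 <- max(sc_s1 * fac[4], 1e-8)
      sc_s2 <- max(sc_s2 * fac[5], 1e-8)
      sc_b <- max(sc_b * fac[6], 1e-8)
      sc_shift <- max(sc_shift * fac[7], 1e-8)
      acc_batch[] <- 0; try_batch[] <- 0
    }
  }

  structure(
    list(draws = draws, burn_in = burn_in,
         summary_window = config$summary_window,
         accept_rates = acc_post / pmax(try_post, 1),
         proposal_scales = list(beta = sc_beta, sigma1 = sc_s1,
                                sigma2 = sc_s2, b = sc_b,
                                shift = sc_shift),
         spec = spec, config = config, subject_ids = st$ids),
    class = "ppk_chain"
  )
}

#' @export
print.ppk_chain <- function(x, ...) {
  cat("ppk_chain:", nrow(x$draws), "iterations (burn-in", x$burn_in, "),",
      length(x$subject_ids), "subjects,", x$spec$error_family, "errors\n")
  cat("  acceptance rates:",
      paste(names(x$accept_rates), sprintf("%.2f", x$accept_rates),
            collapse = ", "), "\n")
  invisible(x)
}

# retained (post burn-in) draws
retained_draws <- function(chain) {
  chain$draws[(chain$burn_in + 1L):nrow(chain$draws), , drop = FALSE]
}

#' Posterior summaries from the end of a chain
#'
#' Per-parameter posterior mean and empirical 2.5%/97.5% percentiles
#' computed from the last `window` iterations of the chain.
#'
#' @param chain A `ppk_chain` from [run_chain()].
#' @param window Number of final iterations to summarize (defaults to the
#'   chain's configured `summary_window`; must not exceed the retained
#'   length).
#' @return A data frame with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
summarize_chain <- function(chain, window = chain$summary_window) {
  stopifnot(inherits(chain, "ppk_chain"))
  ret <- retained_draws(chain)
  window <- as.integer(window)
  if (window < 1 || window > nrow(ret))
    stop("window must lie in [1, ", nrow(ret), "] (retained iterations)")
  w <- ret[(nrow(ret) - window + 1L):nrow(ret), , drop = FALSE]
  q <- apply(w, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(w), mean = colMeans(w),
             lower = q[1, ], upper = q[2, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

# integrated autocorrelation time by Geyer's initial positive sequence
ess_one <- function(x) {
  n <- length(x)
  if (n < 2L || stats::var(x) == 0) return(1)
  rho <- drop(stats::acf(x, lag.max = min(n - 1L, 2000L),
                         plot = FALSE)$acf)[-1]
  tau <- 1
  j <- 1L
  while (j + 1L <= length(rho)) {
    g <- rho[j] + rho[j + 1L]
    if (g <= 0) break
    tau <- tau + 2 * g
    j <- j + 2L
  }
  min(max(n / tau, 1), n)
}

#' Effective sample size and trace series
#'
#' Autocovariance-based single-chain ESS (initial-positive-sequence
#' truncation of the integrated autocorrelation time) per parameter, plus
#' the retained trace series for plotting or export.
#'
#' @param chain A `ppk_chain`.
#' @return A list with `ess` (named numeric vector) and `trace` (matrix of
#'   retained draws).
#' @export
ess_and_trace <- function(chain) {
  stopifnot(inherits(chain, "ppk_chain"))
  ret <- retained_draws(chain)
  list(ess = apply(ret, 2, ess_one), trace = ret)
}
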