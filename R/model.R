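#' Fractional-polynomial design matrix
#'
#' Row \eqn{j} is \eqn{(1, t_j^{p_1}, t_j^{p_2})}; with the default powers
#' `c(1, -1)` this is \eqn{(1, t_j, 1/t_j)}.
#'
#' @param times Strictly positive numeric vector of sampling times (hours).
#' @param powers Length-2 vector of distinct exponents.
#' @return An `n x 3` numeric matrix.
#' @export
#' @examples
#' build_design_matrix(c(0.5, 1, 2))
build_design_matrix <- function(times, powers = c(1, -1)) {
  times <- as.numeric(times)
  bad <- which(!is.finite(times) | times <= 0)
  if (length(bad))
    stop("non-positive time at index ", bad[1L],
         " (the basis contains t^", powers[2], ")")
  powers <- as.numeric(powers)
  stopifnot(length(powers) == 2L, powers[1] != powers[2])
  cbind(1, times^powers[1], times^powers[2], deparse.level = 0)
}

#' Linear predictor of the log-concentration mean
#'
#' Computes \eqn{X\beta + b + \mathrm{offset}}, the modelled mean of the
#' log concentrations for one subject.
#'
#' @param X Design matrix with 3 columns (see [build_design_matrix()]).
#' @param beta Fixed-effect triple.
#' @param b Scalar subject random intercept.
#' @param offset Scalar offset (e.g. `log(dose)`).
#' @return Numeric vector of length `nrow(X)`.
#' @export
linear_predictor <- function(X, beta, b = 0, offset = 0) {
  X <- as.matrix(X)
  if (ncol(X) != 3L) stop("design matrix must have 3 columns, has ", ncol(X))
  beta <- as.numeric(beta)
  if (length(beta) != 3L) stop("beta must have length 3")
  drop(X %*% beta) + b + offset
}

#' One-compartment concentration curve
#'
#' The reference first-order absorption model
#' \deqn{c(t) = \frac{D k_a}{V (k_a - k_e)} \left(e^{-k_e t} - e^{-k_a t}\right),}
#' used by the simulator documentation and as the mechanistic curve the
#' fractional-polynomial model approximates on the log scale.
#'
#' @param dose Dose \eqn{D} (mass).
#' @param V Apparent volume of distribution (> 0).
#' @param ka Absorption rate constant (1/h, > 0).
#' @param ke Elimination rate constant (1/h, >= 0, different from `ka`).
#' @param t Time(s) in hours (>= 0); vectorized.
#' @return Concentration(s), non-negative for `t >= 0`.
#' @export
#' @examples
#' one_compartment_conc(10, 1, ka = 1.5, ke = 0.1, t = c(0, 1, 4, 12))
one_compartment_conc <- function(dose, V, ka, ke, t) {
  stopifnot(V > 0, ka > 0, ke >= 0, all(t >= 0))
  if (ka == ke)
    stop("ka == ke: degenerate one-compartment form not supported")
  dose * ka / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Isotropic multivariate Student t log-density
#'
#' Log-density of the n-dimensional multivariate t distribution with
#' location `mu`, scatter matrix `scatter * I` and `nu` degrees of freedom:
#' \deqn{\log\Gamma\!\left(\tfrac{\nu+n}{2}\right) -
#'   \log\Gamma\!\left(\tfrac{\nu}{2}\right) - \tfrac{n}{2}\log(\nu\pi)
#'   - \tfrac{n}{2}\log\sigma_2
#'   - \tfrac{\nu+n}{2}\log\!\left(1 + \delta/\nu\right),}
#' with \eqn{\delta = \|y-\mu\|^2/\sigma_2}. Note `scatter` is not the
#' variance: the marginal variance is `scatter * nu / (nu - 2)` for
#' `nu > 2`.
#'
#' @param y,mu Numeric vectors of equal length.
#' @param scatter Positive scalar scatter element \eqn{\sigma_2}.
#' @param nu Positive degrees of freedom.
#' @return Scalar log-density.
#' @export
#' @examples
#' mvt_logpdf(0, 0, 1, 1)  # standard Cauchy at the mode: log(1/pi)
mvt_logpdf <- function(y, mu, scatter, nu) {
  if (!is.finite(scatter) || scatter <= 0) stop("scatter must be > 0")
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  y <- as.numeric(y); mu <- as.numeric(mu)
  if (length(y) != length(mu)) stop("y and mu must have equal length")
  n <- length(y)
  delta <- sum((y - mu)^2) / scatter
  lgamma((nu + n) / 2) - lgamma(nu / 2) - (n / 2) * log(nu * pi) -
    (n / 2) * log(scatter) - ((nu + n) / 2) * log1p(delta / nu)
}

#' Isotropic multivariate normal log-density
#'
#' @param y,mu Numeric vectors of equal length.
#' @param variance Positive scalar variance.
#' @return Scalar log-density.
#' @export
mvn_logpdf <- function(y, mu, variance) {
  if (!is.finite(variance) || variance <= 0) stop("variance must be > 0")
  y <- as.numeric(y); mu <- as.numeric(mu)
  if (length(y) != length(mu)) stop("y and mu must have equal length")
  sum(stats::dnorm(y, mu, sqrt(variance), log = TRUE))
}

#' Gamma log-likelihood with log link
#'
#' Sum of gamma log-densities with common shape and per-observation mean
#' `exp(eta)` (so rate = `shape * exp(-eta)`). Used for the gamma-GLM AIC
#' comparison only.
#'
#' @param y Strictly positive observations (raw concentrations).
#' @param eta Vector of log-means, same length as `y`.
#' @param shape Positive shape parameter.
#' @return Scalar log-likelihood.
#' @export
gamma_loglik_loglink <- function(y, eta, shape) {
  y <- as.numeric(y); eta <- as.numeric(eta)
  if (length(y) != length(eta)) stop("y and eta must have equal length")
  if (any(!is.finite(y) | y <= 0)) stop("y must be strictly positive")
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0")
  sum(stats::dgamma(y, shape = shape, rate = shape * exp(-eta), log = TRUE))
}

# Per-subject log-density of the residual family given the vector of
# per-subject residual sums of squares (on the log scale). Vectorized over
# subjects; the core computation of both conditional_loglik and the sampler.
family_loglik_ss <- function(ss, n_i, sigma2, family, nu = NULL) {
  if (family == "normal") {
    -0.5 * n_i * log(2 * pi * sigma2) - ss / (2 * sigma2)
  } else {  # t
    lgamma((nu + n_i) / 2) - lgamma(nu / 2) -
      (n_i / 2) * log(nu * pi * sigma2) -
      ((nu + n_i) / 2) * log1p(ss / (nu * sigma2))
  }
}

#' First-stage (conditional) log-likelihood
#'
#' Log-likelihood of the data given all parameters, summed over subjects:
#' multivariate t or normal on the log concentrations at the subject's
#' linear predictor, or gamma on the raw concentrations with the linear
#' predictor as log-mean.
#'
#' @param data A [pk_dataset()].
#' @param state A [parameter_state()] whose `b` has one element per subject
#'   (in dataset order).
#' @param spec A [pk_model_spec()].
#' @return Scalar log-likelihood.
#' @export
conditional_loglik <- function(data, state, spec) {
  stopifnot(inherits(data, "pk_dataset"), inherits(state, "parameter_state"),
            inherits(spec, "pk_model_spec"))
  st <- stack_dataset(data, spec)
  if (length(state$b) != st$m)
    stop("state$b has ", length(state$b), " elements for ", st$m, " subjects")
  eta <- drop(st$X %*% state$beta) + state$b[st$grp] + st$offset
  if (spec$error_family == "gamma") {
    if (is.null(spec$gamma_shape))
      stop("gamma family requires spec$gamma_shape")
    return(gamma_loglik_loglink(st$conc, eta, spec$gamma_shape))
  }
  ss <- drop(rowsum(( st$y_log - eta )^2, st$grp, reorder = FALSE))
  sum(family_loglik_ss(ss, st$n_i, state$sigma2, spec$error_family, spec$nu))
}

#' Marginal log-likelihood under the normal/normal hierarchy
#'
#' Closed-form per-subject multivariate normal log-density with
#' compound-symmetric covariance \eqn{\sigma_2 I + \sigma_1 J} (random
#' intercept integrated out analytically). Serves as an exact cross-check
#' for quadrature marginalization of [conditional_loglik()].
#'
#' @param data A [pk_dataset()].
#' @param beta Fixed-effect triple.
#' @param sigma1 Random-effect variance (>= 0; 0 collapses to the
#'   conditional likelihood at `b = 0`).
#' @param sigma2 Residual variance (> 0).
#' @param spec A [pk_model_spec()] with normal family.
#' @return Scalar log-likelihood.
#' @export
marginal_normal_loglik <- function(data, beta, sigma1, sigma2, spec) {
  stopifnot(inherits(spec, "pk_model_spec"))
  if (spec$error_family != "normal")
    stop("marginal_normal_loglik applies to the normal family only")
  stopifnot(sigma1 >= 0, sigma2 > 0)
  st <- stack_dataset(data, spec)
  eta <- drop(st$X %*% as.numeric(beta)) + st$offset
  r <- st$y_log - eta
  ss <- drop(rowsum(r^2, st$grp, reorder = FALSE))
  rs <- drop(rowsum(r, st$grp, reorder = FALSE))
  n <- st$n_i
  # Sherman-Morrison: (s2 I + s1 J)^{-1} = I/s2 - s1/(s2 (s2 + n s1)) J
  logdet <- (n - 1) * log(sigma2) + log(sigma2 + n * sigma1)
  quad <- ss / sigma2 - sigma1 * rs^2 / (sigma2 * (sigma2 + n * sigma1))
  sum(-0.5 * (n * log(2 * pi) + logdet + quad))
}
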