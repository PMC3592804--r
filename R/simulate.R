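#' Simulation design for synthetic concentration-time studies
#'
#' Encodes the generating conditions of a synthetic population-PK study:
#' subjects share a sampling schedule and dose; per subject a random
#' intercept is drawn, log-concentrations are the fractional-polynomial
#' mean plus residual noise (isotropic normal or multivariate t), and an
#' optional fraction of observations receives an additive log-scale shift
#' (outlier contamination).
#'
#' @param n_subjects Number of subjects (default 10).
#' @param dose Common dose in mg (default 10).
#' @param schedule Strictly increasing positive sampling times in hours;
#'   default the 12-point schedule
#'   `c(0.2, 0.5, 1, 2, 4, 8, 14, 22, 28, 30, 32, 36)`.
#' @param beta_true Generating fixed effects (beta1, beta2 negative).
#' @param sigma1_true Generating random-intercept variance.
#' @param sigma2_true Generating residual variance (normal) or scatter (t).
#' @param error_family `"normal"` or `"t"` residuals.
#' @param nu Degrees of freedom of t residuals (default 4).
#' @param outlier_fraction Fraction of observations to contaminate,
#'   in `[0, 0.5)`.
#' @param outlier_shift Additive shift on the log-concentration scale for
#'   contaminated observations (default +1).
#' @param powers Fractional-polynomial exponents of the generating mean.
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @return An object of class `simulation_design`.
#' @seealso [preset_example()], [simulate_dataset()]
#' @export
simulation_design <- function(n_subjects = 10, dose = 10,
                              schedule = c(0.2, 0.5, 1, 2, 4, 8, 14, 22,
                                           28, 30, 32, 36),
                              beta_true = c(0.4, -0.04, -0.2),
                              sigma1_true = 0.008, sigma2_true = 0.008,
                              error_family = c("normal", "t"), nu = 4,
                              outlier_fraction = 0, outlier_shift = 1,
                              powers = c(1, -1), seed = NULL) {
  error_family <- match.arg(error_family)
  schedule <- as.numeric(schedule)
  if (any(schedule <= 0) || any(diff(schedule) <= 0))
    stop("schedule must be strictly positive and strictly increasing")
  beta_true <- as.numeric(beta_true)
  stopifnot(length(beta_true) == 3L, beta_true[2] < 0, beta_true[3] < 0,
            n_subjects >= 1, dose > 0, sigma1_true >= 0, sigma2_true >= 0)
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("outlier_fraction must lie in [0, 0.5)")
  if (error_family == "t" && (!is.finite(nu) || nu <= 2))
    stop("t residual simulation needs nu > 2")
  structure(
    list(n_subjects = as.integer(n_subjects), dose = dose,
         schedule = schedule, beta_true = beta_true,
         sigma1_true = sigma1_true, sigma2_true = sigma2_true,
         error_family = error_family, nu = nu,
         outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
         powers = as.numeric(powers),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_design"
  )
}

#' Preset simulation studies
#'
#' The three canonical designs of the simulation study:
#' \describe{
#'   \item{1}{clean: `beta = (0.4, -0.04, -0.2)`, `sigma1 = sigma2 = 0.008`,
#'     normal residuals, no outliers;}
#'   \item{2}{contaminated normal: `beta = (0.8, -0.04, -0.2)`,
#'     `sigma1 = sigma2 = 0.008`, normal residuals, 5% shift outliers;}
#'   \item{3}{heavy-tailed and contaminated: `beta = (0.8, -0.04, -0.2)`,
#'     `sigma1 = 0.01`, `sigma2 = 0.001`, multivariate t residuals
#'     (`nu = 4`), 5% shift outliers.}
#' }
#' All use 10 subjects, a 10 mg dose and the 12-point schedule over 36 h.
#'
#' @param k Example number: 1, 2 or 3.
#' @param seed Optional seed stored in the design.
#' @return A [simulation_design()].
#' @export
preset_example <- function(k, seed = NULL) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  switch(as.character(k),
    "1" = simulation_design(beta_true = c(0.4, -0.04, -0.2),
                            sigma1_true = 0.008, sigma2_true = 0.008,
                            error_family = "normal", seed = seed),
    "2" = simulation_design(beta_true = c(0.8, -0.04, -0.2),
                            sigma1_true = 0.008, sigma2_true = 0.008,
                            error_family = "normal",
                            outlier_fraction = 0.05, seed = seed),
    "3" = simulation_design(beta_true = c(0.8, -0.04, -0.2),
                            sigma1_true = 0.01, sigma2_true = 0.001,
                            error_family = "t", nu = 4,
                            outlier_fraction = 0.05, seed = seed)
  )
}

#' Simulate a dataset from a design
#'
#' Per subject, draws `b_i ~ N(0, sigma1_true)`, sets the log-concentration
#' mean to the fractional-polynomial curve plus `b_i`, adds residual noise
#' (iid normal, or one multivariate-t block per subject with a shared
#' gamma mixing variable), exponentiates, and finally applies outlier
#' contamination when the design requests it.
#'
#' @param design A [simulation_design()].
#' @return A list with `data` (a [pk_dataset()]) and `truth` (the
#'   generating record: design, drawn `b`, contamination `mask`).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  m <- design$n_subjects
  X <- build_design_matrix(design$schedule, design$powers)
  eta0 <- drop(X %*% design$beta_true)
  n <- length(design$schedule)
  b <- stats::rnorm(m, 0, sqrt(design$sigma1_true))
  subjects <- vector("list", m)
  for (i in seq_len(m)) {
    if (design$error_family == "normal" || design$sigma2_true == 0) {
      e <- stats::rnorm(n, 0, sqrt(design$sigma2_true))
    } else {
      g <- stats::rgamma(1, shape = design$nu / 2, rate = design$nu / 2)
      e <- stats::rnorm(n, 0, 1) * sqrt(design$sigma2_true / g)
    }
    subjects[[i]] <- observation_block(
      sprintf("S%02d", i), design$schedule, exp(eta0 + b[i] + e), design$dose)
  }
  data <- pk_dataset(subjects)
  mask <- rep(FALSE, n * m)
  if (design$outlier_fraction > 0) {
    contaminated <- inject_outliers(data, design$outlier_fraction,
                                    design$outlier_shift)
    data <- contaminated$data
    mask <- contaminated$mask
  }
  list(data = data,
       truth = list(design = design, b = b, mask = mask))
}

#' Inject shift outliers into a dataset
#'
#' Selects `round(fraction * N)` observations uniformly without replacement
#' (N = total observations, stacked in subject order) and adds `shift` to
#' their log-concentration, i.e. multiplies the concentration by
#' `exp(shift)`. All other observations are returned bit-identical.
#'
#' @param data A [pk_dataset()].
#' @param fraction Contamination fraction in `[0, 0.5)`.
#' @param shift Additive log-scale shift.
#' @param seed Optional seed; `NULL` uses the ambient RNG state.
#' @return A list with `data` (contaminated copy) and `mask` (logical
#'   vector over stacked observations, `TRUE` where shifted).
#' @export
inject_outliers <- function(data, fraction, shift, seed = NULL) {
  stopifnot(inherits(data, "pk_dataset"))
  if (fraction < 0 || fraction >= 0.5)
    stop("fraction must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  n_i <- vapply(data$subjects, function(s) length(s$times), integer(1))
  N <- sum(n_i)
  n_out <- round(fraction * N)
  mask <- rep(FALSE, N)
  if (n_out > 0) mask[sample.int(N, n_out)] <- TRUE
  if (!any(mask)) return(list(data = data, mask = mask))
  offsets <- c(0L, cumsum(n_i))
  subjects <- data$subjects
  for (i in seq_along(subjects)) {
    mi <- mask[(offsets[i] + 1L):offsets[i + 1L]]
    if (any(mi)) {
      s <- subjects[[i]]
      s$concentrations[mi] <- s$concentrations[mi] * exp(shift)
      subjects[[i]] <- s
    }
  }
  list(data = pk_dataset(subjects), mask = mask)
}
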