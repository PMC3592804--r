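test_that("design matrix evaluates the fractional-polynomial basis", {
  expect_equal(build_design_matrix(1), matrix(c(1, 1, 1), 1))
  expect_equal(build_design_matrix(2), matrix(c(1, 2, 0.5), 1))
  X <- build_design_matrix(schedule12)
  expect_equal(dim(X), c(12L, 3L))
  # column means frozen from element-wise evaluation of the schedule
  expect_equal(colMeans(X), c(1, 14.8083333333, 0.7599965428),
               tolerance = 1e-9)
  # generic powers
  X2 <- build_design_matrix(c(2, 4), powers = c(0.5, -2))
  expect_equal(X2[, 2], sqrt(c(2, 4)))
  expect_equal(X2[, 3], c(0.25, 0.0625))
  expect_error(build_design_matrix(c(1, 0, 2)), "index 2")
})

test_that("linear predictor is X beta + b + offset", {
  expect_equal(linear_predictor(matrix(c(1, 1, 1), 1), c(0, 0, 0)), 0)
  expect_equal(linear_predictor(matrix(c(1, 2, 0.5), 1),
                                c(0.4, -0.04, -0.2)), 0.22)
  X <- build_design_matrix(c(0.5, 1, 8))
  base <- linear_predictor(X, c(0.4, -0.04, -0.2))
  expect_equal(linear_predictor(X, c(0.4, -0.04, -0.2), b = 0.1),
               base + 0.1)
  expect_equal(linear_predictor(X, c(0.4, -0.04, -0.2), offset = log(2)),
               base + log(2))
  expect_error(linear_predictor(matrix(1, 1, 2), c(1, 2, 3)), "3 columns")
})

test_that("one-compartment curve has the right limits and peak", {
  expect_equal(one_compartment_conc(10, 1, 1.5, 0.1, 0), 0)
  # ke = 0 reduces to (D/V)(1 - exp(-ka t)), saturating at D/V
  expect_equal(one_compartment_conc(10, 1, 1, 0, 1e4), 10)
  # derivative vanishes at the analytic peak time
  ka <- 1.5; ke <- 0.1
  tmax <- log(ka / ke) / (ka - ke)
  h <- 1e-6
  deriv <- (one_compartment_conc(10, 1, ka, ke, tmax + h) -
            one_compartment_conc(10, 1, ka, ke, tmax - h)) / (2 * h)
  expect_lt(abs(deriv), 1e-6)
  expect_error(one_compartment_conc(10, 1, 1, 1, 1), "ka == ke")
})

test_that("multivariate t log-density matches closed forms and oracles", {
  # standard Cauchy at the mode
  expect_equal(mvt_logpdf(0, 0, 1, 1), log(1 / pi), tolerance = 1e-12)
  # normal limit
  z <- seq(-3, 3, by = 0.25)
  for (zi in z) {
    expect_equal(mvt_logpdf(zi, 0, 1, 1e6), stats::dnorm(zi, log = TRUE),
                 tolerance = 1e-4)
  }
  # n = 2 case against the gamma scale-mixture representation:
  # f(y) = E_g[ N(y; mu, (sigma2/g) I) ], g ~ Gamma(nu/2, rate nu/2)
  set.seed(42)
  nu <- 4; s2 <- 2; d <- c(1, 1)
  g <- stats::rgamma(1e6, nu / 2, rate = nu / 2)
  vals <- exp(-log(2 * pi * s2 / g) - sum(d^2) * g / (2 * s2))
  mc <- mean(vals)
  mc_se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(exp(mvt_logpdf(d, c(0, 0), s2, nu)) - mc), 3 * mc_se)
  # frozen value of the same case
  expect_equal(mvt_logpdf(d, c(0, 0), s2, nu), -3.20045490,
               tolerance = 1e-7)
  expect_error(mvt_logpdf(1, 0, -1, 4), "scatter")
  expect_error(mvt_logpdf(1, 0, 1, 0), "nu")
})

test_that("mvt density quadrature-normalizes in one dimension", {
  # whole-line adaptive quadrature: at nu = 1 (Cauchy) more than 1% of the
  # mass lies beyond +/- 50 scale units, so finite brackets are not enough
  for (nu in c(1, 4, 30)) {
    total <- stats::integrate(
      function(x) vapply(x, function(xi) exp(mvt_logpdf(xi, 0, 2, nu)), 0),
      -Inf, Inf, rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-6)
  }
})

test_that("normal log-density factorizes and is the t limit", {
  expect_equal(mvn_logpdf(0, 0, 1), -0.5 * log(2 * pi))
  y <- c(0.3, -1.2); mu <- c(0, 0.5)
  expect_equal(mvn_logpdf(y, mu, 2),
               mvn_logpdf(y[1], mu[1], 2) + mvn_logpdf(y[2], mu[2], 2))
  expect_equal(mvt_logpdf(y, mu, 2, 1e8), mvn_logpdf(y, mu, 2),
               tolerance = 1e-3)
  expect_error(mvn_logpdf(1, 0, 0), "variance")
})

test_that("gamma log-likelihood has exponential special case and normalizes", {
  # shape = 1 is the exponential density
  y <- c(0.5, 2.3); eta <- c(0.1, 0.4)
  expect_equal(gamma_loglik_loglink(y, eta, 1),
               sum(-eta - y * exp(-eta)))
  # density concentrates at the mean as shape grows
  ll <- vapply(c(1, 10, 100, 1000), function(sh)
    gamma_loglik_loglink(exp(0.3), 0.3, sh), 0)
  expect_true(all(diff(ll) > 0))
  # quadrature normalization of an arbitrary case
  total <- stats::integrate(function(x)
    vapply(x, function(xi) exp(gamma_loglik_loglink(xi, 0.7, 3.2)), 0),
    0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(gamma_loglik_loglink(c(1, -1), c(0, 0), 1), "positive")
})

test_that("conditional log-likelihood composes per-subject densities", {
  spec_n <- pk_model_spec("normal")
  d1 <- pk_dataset(list(observation_block("A", 1, exp(0.16), 10)))
  st <- parameter_state(c(0.4, -0.04, -0.2), 0, 0.01, 0.02)
  # single observation exactly at its mean (t = 1: eta = 0.16)
  expect_equal(conditional_loglik(d1, st, spec_n), -0.5 * log(2 * pi * 0.02))
  # additivity over identical subjects
  d2 <- pk_dataset(list(observation_block("A", 1, exp(0.16), 10),
                        observation_block("B", 1, exp(0.16), 10)))
  st2 <- parameter_state(c(0.4, -0.04, -0.2), c(0, 0), 0.01, 0.02)
  expect_equal(conditional_loglik(d2, st2, spec_n),
               2 * conditional_loglik(d1, st, spec_n))
  # t family equals mvt_logpdf summed per subject
  spec_t <- pk_model_spec("t", nu = 5)
  data <- tiny_dataset(n_subjects = 3, b = c(0.1, -0.2, 0), noise_sd = 0.1,
                       seed = 3)
  stt <- parameter_state(c(0.3, -0.05, -0.15), c(0.05, -0.02, 0.01),
                         0.01, 0.04)
  X <- build_design_matrix(c(0.5, 1, 2, 4))
  manual <- 0
  for (i in 1:3) {
    y <- log(data$subjects[[i]]$concentrations)
    manual <- manual +
      mvt_logpdf(y, drop(X %*% stt$beta) + stt$b[i], stt$sigma2, 5)
  }
  expect_equal(conditional_loglik(data, stt, spec_t), manual)
  # invariant to subject ordering
  data_rev <- pk_dataset(rev(data$subjects))
  stt_rev <- parameter_state(stt$beta, rev(stt$b), stt$sigma1, stt$sigma2)
  expect_equal(conditional_loglik(data_rev, stt_rev, spec_t),
               conditional_loglik(data, stt, spec_t))
})

test_that("compound-symmetric marginal equals quadrature marginalization", {
  spec_n <- pk_model_spec("normal")
  data <- tiny_dataset(n_subjects = 3, b = c(0.08, -0.05, 0.02),
                       noise_sd = 0.1, seed = 7)
  beta <- c(0.35, -0.05, -0.18); s1 <- 0.01; s2 <- 0.04
  # sigma1 = 0 collapses to the conditional likelihood at b = 0
  st0 <- parameter_state(beta, rep(0, 3), 1e-12, s2)
  expect_equal(marginal_normal_loglik(data, beta, 0, s2, spec_n),
               conditional_loglik(data, st0, spec_n), tolerance = 1e-8)
  # one subject, one observation: univariate normal with var s1 + s2
  d1 <- pk_dataset(list(observation_block("A", 2, 1.1, 10)))
  X1 <- build_design_matrix(2)
  expect_equal(marginal_normal_loglik(d1, beta, s1, s2, spec_n),
               mvn_logpdf(log(1.1), drop(X1 %*% beta), s1 + s2))
  # quadrature oracle: integrate the conditional over each subject's b
  manual <- 0
  X <- build_design_matrix(c(0.5, 1, 2, 4))
  for (i in 1:3) {
    y <- log(data$subjects[[i]]$concentrations)
    mu0 <- drop(X %*% beta)
    f <- function(b) vapply(b, function(bi)
      exp(mvn_logpdf(y, mu0 + bi, s2) +
            stats::dnorm(bi, 0, sqrt(s1), log = TRUE)), 0)
    manual <- manual + log(stats::integrate(f, -Inf, Inf,
                                            rel.tol = 1e-11)$value)
  }
  expect_equal(marginal_normal_loglik(data, beta, s1, s2, spec_n), manual,
               tolerance = 1e-6)
})

test_that("dataset and state constructors enforce their invariants", {
  expect_error(observation_block("A", c(1, 2), c(1, -1), 10),
               "concentration")
  expect_error(observation_block("A", c(2, 1), c(1, 1), 10), "increasing")
  expect_error(observation_block("A", c(0, 1), c(1, 1), 10), "position 1")
  expect_error(pk_dataset(list()), "at least one subject")
  expect_error(parameter_state(c(0.4, 0.1, -0.2), 0, 0.01, 0.01),
               "constraints")
  expect_error(parameter_state(c(0.4, -0.1, -0.2), 0, -1, 0.01), "sigma1")
  expect_error(pk_model_spec("t", nu = 2), "nu > 2")
  expect_error(pk_model_spec("t", powers = c(1, 1)), "differ")
})
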