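test_that("log prior combines normal, gamma, and second-stage terms", {
  pr <- prior_spec(beta_mean = c(0.1, -0.1, -0.1), beta_var = c(4, 9, 16),
                   sigma1_shape = 2, sigma1_rate = 3,
                   sigma2_shape = 1.5, sigma2_rate = 2)
  st <- parameter_state(c(0.1, -0.1, -0.1), c(0.05, -0.02), 0.01, 0.02)
  manual <- -0.5 * sum(log(2 * pi * c(4, 9, 16))) +
    stats::dgamma(0.01, 2, rate = 3, log = TRUE) +
    stats::dgamma(0.02, 1.5, rate = 2, log = TRUE) +
    sum(stats::dnorm(c(0.05, -0.02), 0, sqrt(0.01), log = TRUE))
  expect_equal(log_prior(st, pr), manual)
  # moving beta0 away from its prior mean strictly decreases the prior
  lp <- vapply(c(0.1, 0.6, 1.6, 3.1), function(m)
    log_prior(parameter_state(c(m, -0.1, -0.1), st$b, 0.01, 0.02), pr), 0)
  expect_true(all(diff(lp) < 0))
})

test_that("log posterior is likelihood plus prior, additive in subjects", {
  data <- tiny_dataset(n_subjects = 2, b = c(0.1, -0.1), noise_sd = 0.05,
                       seed = 11)
  spec <- pk_model_spec("t", nu = 4)
  pr <- prior_spec()
  st <- parameter_state(c(0.3, -0.05, -0.15), c(0.02, -0.01), 0.01, 0.02)
  expect_equal(log_posterior(st, data, spec, pr),
               conditional_loglik(data, st, spec) + log_prior(st, pr))
  # adding a subject adds its likelihood and its b-prior term
  extra <- observation_block("S3", c(0.5, 1, 2, 4),
                             exp(linear_predictor(
                               build_design_matrix(c(0.5, 1, 2, 4)),
                               c(0.4, -0.04, -0.2)) + 0.03), 10)
  data3 <- pk_dataset(c(data$subjects, list(extra)))
  st3 <- parameter_state(st$beta, c(st$b, 0.03), st$sigma1, st$sigma2)
  d1 <- pk_dataset(list(extra))
  st1 <- parameter_state(st$beta, 0.03, st$sigma1, st$sigma2)
  expect_equal(log_posterior(st3, data3, spec, pr) -
                 log_posterior(st, data, spec, pr),
               conditional_loglik(d1, st1, spec) +
                 stats::dnorm(0.03, 0, sqrt(st$sigma1), log = TRUE))
})

test_that("mh_step accepts null proposals and rejects constraint violations", {
  data <- tiny_dataset(seed = 2)
  spec <- pk_model_spec("normal")
  pr <- prior_spec()
  st <- parameter_state(c(0.3, -0.05, -0.15), c(0, 0), 0.01, 0.02)
  # zero proposal scale: proposal equals current state, p = 1
  cfg0 <- mcmc_config(10, 5, 5,
                      proposal_scales = list(beta = c(0, 0, 0), sigma1 = 0,
                                             sigma2 = 0, b = 0, shift = 0))
  set.seed(1)
  for (blk in c("beta0", "beta1", "sigma1", "b1")) {
    res <- mh_step(st, blk, data, spec, pr, cfg0)
    expect_true(res$accepted)
    expect_equal(res$state, st)
  }
  # beta1 sits just below 0 with a large scale: proposals crossing zero
  # must always be rejected, so beta1 stays negative for every step
  st_edge <- parameter_state(c(0.3, -1e-9, -0.15), c(0, 0), 0.01, 0.02)
  cfg_big <- mcmc_config(10, 5, 5, proposal_scales = list(beta = c(0, 5, 0)))
  set.seed(42)
  crossed <- 0
  cur <- st_edge
  for (i in 1:100) {
    res <- mh_step(cur, "beta1", data, spec, pr, cfg_big)
    expect_lt(res$state$beta[2], 0)
    cur <- res$state
  }
  expect_error(mh_step(st, "nosuch", data, spec, pr, cfg0), "unknown")
})

test_that("chain matches the conjugate posterior on a single-parameter target", {
  # freeze every block except beta0: normal likelihood with known variance
  # and a normal prior on beta0 is conjugate with a closed-form posterior
  times <- c(0.5, 1, 2, 4, 8, 14, 22, 36)
  data <- tiny_dataset(n_subjects = 1, times = times, noise_sd = 0.3,
                       seed = 5)
  spec <- pk_model_spec("normal")
  m0 <- 0.2; v0 <- 0.25; s2 <- 0.09
  pr <- prior_spec(beta_mean = c(m0, -0.1, -0.1), beta_var = c(v0, 100, 100))
  cfg <- mcmc_config(20000, 2000, 18000, seed = 99, adapt = FALSE,
                     proposal_scales = list(beta = c(0.3, 0, 0), sigma1 = 0,
                                            sigma2 = 0, b = 0, shift = 0))
  fit <- run_chain(data, spec, pr, cfg,
                   init = list(beta = c(0.1, -0.1, -0.1), sigma2 = s2))
  y <- log(data$subjects[[1]]$concentrations)
  rest <- drop(build_design_matrix(times) %*% c(0, -0.1, -0.1))
  n <- length(y)
  prec <- n / s2 + 1 / v0
  post_mean <- (sum(y - rest) / s2 + m0 / v0) / prec
  post_sd <- sqrt(1 / prec)
  draws <- fit$draws[2001:20000, "beta0"]
  ess <- ess_and_trace(fit)$ess[["beta0"]]
  mcse <- stats::sd(draws) / sqrt(ess)
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
  expect_equal(stats::sd(draws), post_sd, tolerance = 0.1)
  # stationary-distribution check: decile counts against the closed form
  bins <- cut(stats::pnorm(draws, post_mean, post_sd),
              breaks = seq(0, 1, 0.1))
  # thin to roughly independent draws for the chi-square test
  thin <- draws[seq(1, length(draws), by = ceiling(length(draws) / ess))]
  counts <- table(cut(stats::pnorm(thin, post_mean, post_sd),
                      breaks = seq(0, 1, 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("chains are seed-deterministic and respect constraints", {
  sim <- simulate_dataset(preset_example(1, seed = 8))
  spec <- pk_model_spec("t", nu = 4)
  cfg <- quick_config(seed = 123)
  f1 <- run_chain(sim$data, spec, config = cfg)
  f2 <- run_chain(sim$data, spec, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws[, "beta1"] < 0))
  expect_true(all(f1$draws[, "beta2"] < 0))
  expect_true(all(f1$draws[, "sigma1"] > 0))
  expect_true(all(f1$draws[, "sigma2"] > 0))
  # bad initialization is reported, not silently accepted (normal family:
  # the t likelihood stays finite even at absurdly small scatter)
  expect_error(run_chain(sim$data, pk_model_spec("normal"), config = cfg,
                         init = list(sigma2 = 1e-320)), "initial values")
})

test_that("summaries come from the final window with percentile intervals", {
  sim <- simulate_dataset(preset_example(1, seed = 9))
  fit <- run_chain(sim$data, pk_model_spec("normal"),
                   config = quick_config(seed = 4))
  s_all <- summarize_chain(fit, window = 200)
  # explicit sort-based oracle on one column
  w <- fit$draws[401:600, "beta0"]
  expect_equal(s_all$mean[s_all$parameter == "beta0"], mean(w))
  expect_equal(s_all$lower[s_all$parameter == "beta0"],
               unname(stats::quantile(w, 0.025)))
  # constant series: degenerate interval
  fit2 <- fit
  fit2$draws[, "beta0"] <- 0.5
  s2 <- summarize_chain(fit2, window = 200)
  expect_equal(unlist(s2[s2$parameter == "beta0", c("mean", "lower", "upper")],
                      use.names = FALSE), c(0.5, 0.5, 0.5))
  expect_error(summarize_chain(fit, window = 1e6), "window")
})

test_that("effective sample size tracks the autocorrelation structure", {
  make_chain <- function(x) {
    structure(list(draws = cbind(x = x), burn_in = 0L,
                   summary_window = length(x)), class = "ppk_chain")
  }
  set.seed(31)
  # iid draws: ESS close to n
  n <- 4000
  ess_iid <- ess_and_trace(make_chain(stats::rnorm(n)))$ess[["x"]]
  expect_gt(ess_iid, 0.8 * n)
  expect_lt(ess_iid, 1.2 * n)
  # constant (perfectly correlated) chain
  expect_equal(ess_and_trace(make_chain(rep(1, 500)))$ess[["x"]], 1)
  # AR(1) with known rho: ESS ~ n (1 - rho) / (1 + rho)
  rho <- 0.7
  x <- stats::filter(stats::rnorm(n), rho, method = "recursive")
  ess_ar <- ess_and_trace(make_chain(as.numeric(x)))$ess[["x"]]
  expected <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(ess_ar - expected) / expected, 0.25)
})

test_that("replicate studies summarize across replicates deterministically", {
  design <- preset_example(1, seed = 5)
  spec <- pk_model_spec("t", nu = 4)
  cfg <- quick_config()
  # identical replicate seeds give a degenerate zero-width interval
  rs <- replicate_study(design, spec, config = cfg, n_reps = 2,
                        rep_seeds = c(7, 7))
  expect_equal(rs$estimates[1, ], rs$estimates[2, ])
  expect_equal(rs$summary$lower, rs$summary$upper)
  expect_equal(rs$summary$mean, unname(rs$estimates[1, ]))
})
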