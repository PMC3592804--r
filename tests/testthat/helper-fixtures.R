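# small deterministic fixtures built in code

tiny_dataset <- function(n_subjects = 2, times = c(0.5, 1, 2, 4),
                         beta = c(0.4, -0.04, -0.2), b = NULL,
                         noise_sd = 0, dose = 10, seed = 1) {
  set.seed(seed)
  if (is.null(b)) b <- rep(0, n_subjects)
  X <- build_design_matrix(times)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    eta <- drop(X %*% beta) + b[i] + stats::rnorm(length(times), 0, noise_sd)
    observation_block(paste0("S", i), times, exp(eta), dose)
  })
  pk_dataset(subjects)
}

quick_config <- function(n_iter = 600, burn_in = 400, window = 200,
                         seed = 1) {
  mcmc_config(n_iter, burn_in, window, seed = seed)
}

# paper-style 12-point schedule over 36 h
schedule12 <- c(0.2, 0.5, 1, 2, 4, 8, 14, 22, 28, 30, 32, 36)
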