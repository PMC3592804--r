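# open an image device; png where the build supports it, pdf otherwise
open_image_device <- function(stem) {
  if (capabilities("png")) {
    file <- paste0(stem, ".png")
    grDevices::png(file, width = 900, height = 600)
  } else {
    file <- paste0(stem, ".pdf")
    grDevices::pdf(file, width = 9, height = 6)
  }
  file
}

#' Export diagnostic plots
#'
#' Writes, with deterministic file names under `dir`:
#' \itemize{
#'   \item one trace plot per core parameter
#'     (`<prefix>_trace_<parameter>`), over the retained iterations;
#'   \item population predictions vs observations (`<prefix>_pred_dv`),
#'     using the posterior-mean fixed effects with `b = 0`;
#'   \item individual predictions vs observations (`<prefix>_ipred_dv`),
#'     adding each subject's posterior-mean random intercept.
#' }
#'
#' @param chain A `ppk_chain`.
#' @param data The [pk_dataset()] the chain was fitted to.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"ppk"`).
#' @return Character vector of files written, invisibly.
#' @export
export_plots <- function(chain, data, dir, prefix = "ppk") {
  stopifnot(inherits(chain, "ppk_chain"), inherits(data, "pk_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  ret <- retained_draws(chain)
  core <- c("beta0", "beta1", "beta2", "sigma1", "sigma2")
  for (p in core) {
    f <- open_image_device(file.path(dir, paste0(prefix, "_trace_", p)))
    graphics::plot(chain$burn_in + seq_len(nrow(ret)), ret[, p],
                   type = "l", xlab = "iteration", ylab = p,
                   main = paste("Trace of", p))
    grDevices::dev.off()
    files <- c(files, f)
  }
  s <- summarize_chain(chain)
  est <- stats::setNames(s$mean, s$parameter)
  beta_hat <- est[c("beta0", "beta1", "beta2")]
  b_hat <- est[grep("^b_", names(est))]
  st <- stack_dataset(data, chain$spec)
  eta0 <- drop(st$X %*% beta_hat) + st$offset
  pred <- exp(eta0)
  ipred <- exp(eta0 + b_hat[st$grp])
  dv <- st$conc
  for (kind in c("pred", "ipred")) {
    f <- open_image_device(file.path(dir, paste0(prefix, "_", kind, "_dv")))
    x <- if (kind == "pred") pred else ipred
    graphics::plot(x, dv, xlab = paste0(kind, " (model)"),
                   ylab = "DV (observed)",
                   main = paste(toupper(kind), "vs observed concentrations"))
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

# predictions used by plots and tests: population (b = 0) and individual
# (posterior-mean b_i) predicted concentrations, one value per observation
predicted_concentrations <- function(chain, data) {
  s <- summarize_chain(chain)
  est <- stats::setNames(s$mean, s$parameter)
  st <- stack_dataset(data, chain$spec)
  eta0 <- drop(st$X %*% est[c("beta0", "beta1", "beta2")]) + st$offset
  b_hat <- est[grep("^b_", names(est))]
  list(pred = exp(eta0), ipred = exp(eta0 + b_hat[st$grp]), dv = st$conc)
}
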