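# population log-concentration curve (b = 0)
curve_eta <- function(t, beta, powers) {
  beta[1] + beta[2] * t^powers[1] + beta[3] * t^powers[2]
}

#' Time of peak concentration
#'
#' Argmax over t > 0 of the fitted population curve. For the default
#' powers (1, -1) the closed form is \eqn{t_{max} = \sqrt{\beta_2/\beta_1}};
#' other powers are handled by a bracketed golden-section search (relative
#' tolerance 1e-8) after locating an interior maximum on a log-spaced grid.
#'
#' @param beta Fixed-effect triple with `beta[2] < 0`, `beta[3] < 0`.
#' @param spec A [pk_model_spec()] (supplies the powers).
#' @param force_numeric Use the numeric search even when the closed form
#'   applies (cross-validation of the two routes).
#' @return Peak time in hours.
#' @export
#' @examples
#' curve_tmax(c(0.4, -0.04, -0.2), pk_model_spec("t"))  # sqrt(5)
curve_tmax <- function(beta, spec = pk_model_spec("t"),
                       force_numeric = FALSE) {
  beta <- as.numeric(beta)
  stopifnot(length(beta) == 3L)
  if (beta[2] >= 0 || beta[3] >= 0)
    stop("tmax requires beta1 < 0 and beta2 < 0")
  p <- spec$powers
  if (!force_numeric && isTRUE(all.equal(p, c(1, -1))))
    return(sqrt(beta[3] / beta[2]))
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 400))
  v <- curve_eta(grid, beta, p)
  i <- which.max(v)
  if (i == 1L || i == length(grid))
    stop("fitted curve has no interior maximum for these powers")
  opt <- stats::optimize(function(t) curve_eta(t, beta, p),
                         interval = c(grid[i - 1L], grid[i + 1L]),
                         maximum = TRUE, tol = 1e-8 * grid[i])
  opt$maximum
}

#' Peak concentration
#'
#' The fitted population curve evaluated at [curve_tmax()], exponentiated:
#' for the default powers, \eqn{c_{max} = \exp(\beta_0 + \mathrm{offset}
#' - 2\sqrt{\beta_1\beta_2})}.
#'
#' @inheritParams curve_tmax
#' @param offset Scalar added to the linear predictor (e.g. `log(dose)`).
#' @return Peak concentration.
#' @export
curve_cmax <- function(beta, spec = pk_model_spec("t"), offset = 0) {
  tmax <- curve_tmax(beta, spec)
  exp(curve_eta(tmax, as.numeric(beta), spec$powers) + offset)
}

#' Half-life of the fitted curve
#'
#' Two labeled variants are returned, because they answer different
#' questions and coincide only when elimination is purely exponential:
#' \describe{
#'   \item{terminal}{\eqn{\log 2 / (-\beta_1)}, the half-life of the
#'     exponential tail (defined when one power equals 1);}
#'   \item{post_peak}{the numeric time past the peak at which the curve has
#'     fallen to half the peak value, i.e. the t > tmax solving
#'     \eqn{\eta(t) = \eta(t_{max}) - \log 2} by bisection (absolute
#'     tolerance 1e-8).}
#' }
#'
#' @inheritParams curve_tmax
#' @return Named numeric vector `c(terminal = ..., post_peak = ...)`;
#'   `terminal` is `NA` if no power equals 1.
#' @export
curve_thalf <- function(beta, spec = pk_model_spec("t")) {
  beta <- as.numeric(beta)
  tmax <- curve_tmax(beta, spec)
  p <- spec$powers
  lin <- which(p == 1)
  terminal <- if (length(lin)) log(2) / (-beta[1L + lin[1L]]) else NA_real_
  target <- curve_eta(tmax, beta, p) - log(2)
  f <- function(t) curve_eta(t, beta, p) - target
  # bracket cap independent of tmax: as beta2 -> 0 the peak moves toward 0
  # while the half-time stays near the terminal value
  cap <- 1e3 * max(tmax, 1)
  upper <- 2 * tmax
  while (f(upper) > 0 && upper < cap) upper <- upper * 2
  if (f(upper) > 0)
    stop("no post-peak half-time found within [tmax, ", cap, "]")
  root <- stats::uniroot(f, c(tmax, upper), tol = 1e-8)$root
  c(terminal = terminal, post_peak = root - tmax)
}

#' Posterior summaries of derived PK parameters
#'
#' Maps every retained fixed-effect draw in the summary window through
#' [curve_tmax()], [curve_cmax()] and [curve_thalf()] (population curve,
#' `b = 0`) and summarizes each derived quantity by its mean and empirical
#' 2.5%/97.5% interval. Draws where a quantity is undefined are dropped and
#' counted; more than 50% undefined draws is an error.
#'
#' @param chain A `ppk_chain`.
#' @param spec A [pk_model_spec()].
#' @param offset Scalar offset for [curve_cmax()].
#' @param window Final iterations to use (default the chain's summary
#'   window).
#' @return A list with `summary` (data frame over tmax, cmax,
#'   thalf_terminal, thalf_post_peak), `n_used`, `n_dropped`.
#' @export
posterior_derived <- function(chain, spec = chain$spec, offset = 0,
                              window = chain$summary_window) {
  stopifnot(inherits(chain, "ppk_chain"))
  ret <- retained_draws(chain)
  stopifnot(window >= 1, window <= nrow(ret))
  w <- ret[(nrow(ret) - window + 1L):nrow(ret),
           c("beta0", "beta1", "beta2"), drop = FALSE]
  vals <- matrix(NA_real_, nrow(w), 4L,
                 dimnames = list(NULL, c("tmax", "cmax", "thalf_terminal",
                                         "thalf_post_peak")))
  for (j in seq_len(nrow(w))) {
    res <- tryCatch({
      tm <- curve_tmax(w[j, ], spec)
      th <- curve_thalf(w[j, ], spec)
      c(tm, curve_cmax(w[j, ], spec, offset), th[["terminal"]],
        th[["post_peak"]])
    }, error = function(e) rep(NA_real_, 4L))
    vals[j, ] <- res
  }
  ok <- stats::complete.cases(vals[, c("tmax", "cmax", "thalf_post_peak")])
  if (mean(ok) < 0.5)
    stop("derived parameters undefined for more than half the draws")
  v <- vals[ok, , drop = FALSE]
  q <- apply(v, 2, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE, na.rm = TRUE)
  list(summary = data.frame(parameter = colnames(v),
                            mean = colMeans(v, na.rm = TRUE),
                            lower = q[1, ], upper = q[2, ],
                            row.names = NULL, stringsAsFactors = FALSE),
       n_used = sum(ok), n_dropped = sum(!ok))
}
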