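#' Read a concentration-time table
#'
#' Reads a comma-delimited file with a mandatory header and columns
#' `subject_id`, `time`, `conc`, `dose` (one row per observation), grouping
#' rows by subject in order of first appearance and preserving the
#' within-subject row order. Validation failures are reported with the
#' offending file line number (header is line 1).
#'
#' @param path Path to the CSV file.
#' @return A [pk_dataset()].
#' @export
read_pk_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "time", "conc", "dose")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop("no data rows in ", path)
  lines <- seq_len(nrow(df)) + 1L  # file line numbers (header = 1)
  for (col in c("time", "conc", "dose")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric ", col, " at line ", lines[bad[1L]])
    df[[col]] <- v
  }
  bad <- which(df$time <= 0)
  if (length(bad))
    stop("non-positive time at line ", lines[bad[1L]])
  bad <- which(df$conc <= 0)
  if (length(bad))
    stop("non-positive concentration at line ", lines[bad[1L]])
  ids <- unique(df$subject_id)
  subjects <- lapply(ids, function(id) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    if (length(unique(rows$dose)) > 1L)
      stop("subject '", id, "' has inconsistent dose values")
    tryCatch(
      observation_block(id, rows$time, rows$conc, rows$dose[1L]),
      error = function(e)
        stop(conditionMessage(e), " (subject rows start at line ",
             lines[which(df$subject_id == id)[1L]], ")", call. = FALSE))
  })
  pk_dataset(subjects)
}

#' Write a dataset as a concentration-time table
#'
#' Inverse of [read_pk_csv()]: one row per observation, columns
#' `subject_id`, `time`, `conc`, `dose`.
#'
#' @param data A [pk_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write retained MCMC draws as delimited text
#'
#' One row per retained (post-burn-in) iteration with a named header and an
#' `iteration` index column.
#'
#' @param chain A `ppk_chain`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "ppk_chain"))
  ret <- retained_draws(chain)
  out <- data.frame(iteration = chain$burn_in + seq_len(nrow(ret)), ret)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structured fit summary document
#'
#' Collects posterior means and 95% intervals, acceptance rates, the model
#' specification and MCMC configuration (and optionally derived PK
#' parameters) into a list suitable for JSON export.
#'
#' @param chain A `ppk_chain`.
#' @param derived Optional result of [posterior_derived()].
#' @return A named list.
#' @seealso [write_summary_json()]
#' @export
summary_document <- function(chain, derived = NULL) {
  s <- summarize_chain(chain)
  doc <- list(
    model = list(error_family = chain$spec$error_family,
                 powers = chain$spec$powers,
                 nu = chain$spec$nu,
                 dose_offset = chain$spec$dose_offset),
    mcmc = list(n_iter = chain$config$n_iter,
                burn_in = chain$burn_in,
                summary_window = chain$summary_window,
                seed = chain$config$seed,
                accept_rates = as.list(chain$accept_rates)),
    posterior = lapply(seq_len(nrow(s)), function(i)
      list(parameter = s$parameter[i], mean = s$mean[i],
           lower = s$lower[i], upper = s$upper[i]))
  )
  if (!is.null(derived)) {
    d <- derived$summary
    doc$derived_pk <- lapply(seq_len(nrow(d)), function(i)
      list(parameter = d$parameter[i], mean = d$mean[i],
           lower = d$lower[i], upper = d$upper[i]))
    doc$derived_pk_dropped <- derived$n_dropped
  }
  doc
}

#' Write a fit summary as JSON
#'
#' @param chain A `ppk_chain`.
#' @param path Output path.
#' @param derived Optional result of [posterior_derived()].
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(chain, path, derived = NULL) {
  jsonlite::write_json(summary_document(chain, derived), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
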