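#' Single-subject concentration-time block
#'
#' Bundles one subject's sampling times, measured concentrations and
#' administered dose. Times must be strictly increasing and strictly
#' positive (the fractional-polynomial basis contains \eqn{t^{-1}}), and
#' concentrations strictly positive (the model works on the log scale).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param times Numeric vector of sampling times in hours.
#' @param concentrations Numeric vector of measured concentrations
#'   (mass/volume), same length as `times`.
#' @param dose Scalar dose (mass) given to this subject.
#' @return An object of class `observation_block`.
#' @seealso [pk_dataset()]
#' @export
#' @examples
#' observation_block("S1", c(0.5, 1, 2), c(1.1, 1.4, 1.2), dose = 10)
observation_block <- function(subject_id, times, concentrations, dose) {
  subject_id <- as.character(subject_id)
  stopifnot(length(subject_id) == 1L, nchar(subject_id) > 0L)
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) < 1L)
    stop("subject '", subject_id, "': needs at least one observation")
  if (length(times) != length(concentrations))
    stop("subject '", subject_id, "': times and concentrations differ in length (",
         length(times), " vs ", length(concentrations), ")")
  bad_t <- which(!is.finite(times) | times <= 0)
  if (length(bad_t))
    stop("subject '", subject_id, "': non-positive or non-finite time at position ",
         bad_t[1L])
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("subject '", subject_id, "': times must be strictly increasing")
  bad_c <- which(!is.finite(concentrations) | concentrations <= 0)
  if (length(bad_c))
    stop("subject '", subject_id,
         "': non-positive or non-finite concentration at position ", bad_c[1L])
  if (!is.finite(dose) || length(dose) != 1L || dose <= 0)
    stop("subject '", subject_id, "': dose must be a positive scalar")
  structure(
    list(subject_id = subject_id, times = times,
         concentrations = concentrations, dose = as.numeric(dose)),
    class = "observation_block"
  )
}

#' Population pharmacokinetic dataset
#'
#' An ordered collection of per-subject [observation_block()]s, the data
#' object consumed by the likelihood, the sampler and the simulator.
#'
#' @param subjects List of `observation_block` objects with unique ids.
#' @return An object of class `pk_dataset`.
#' @export
#' @examples
#' d <- pk_dataset(list(
#'   observation_block("S1", c(1, 2), c(1.2, 1.1), 10),
#'   observation_block("S2", c(1, 2, 4), c(1.3, 1.2, 0.9), 10)
#' ))
#' as.data.frame(d)
pk_dataset <- function(subjects) {
  if (!is.list(subjects) || length(subjects) < 1L)
    stop("a pk_dataset needs at least one subject")
  ok <- vapply(subjects, inherits, logical(1), what = "observation_block")
  if (!all(ok))
    stop("all subjects must be observation_block objects (element ",
         which(!ok)[1L], " is not)")
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    stop("duplicated subject_id: ", ids[duplicated(ids)][1L])
  names(subjects) <- ids
  structure(list(subjects = subjects), class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  n <- vapply(x$subjects, function(s) length(s$times), integer(1))
  cat("pk_dataset:", length(x$subjects), "subjects,", sum(n), "observations\n")
  cat("  obs per subject:", paste(n, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.pk_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$subjects, function(s) {
    data.frame(subject_id = s$subject_id, time = s$times,
               conc = s$concentrations, dose = s$dose,
               stringsAsFactors = FALSE, row.names = NULL)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Number of observations in a dataset
#'
#' @param data A [pk_dataset()].
#' @return Integer count of concentration measurements across all subjects.
#' @export
n_observations <- function(data) {
  stopifnot(inherits(data, "pk_dataset"))
  sum(vapply(data$subjects, function(s) length(s$times), integer(1)))
}

# Stack a dataset into flat vectors for fast likelihood evaluation.
# Returns log-concentrations, subject index, per-subject sizes, design
# matrix rows, and the dose offset (log dose when spec$dose_offset).
stack_dataset <- function(data, spec) {
  stopifnot(inherits(data, "pk_dataset"))
  subs <- data$subjects
  n_i <- vapply(subs, function(s) length(s$times), integer(1))
  grp <- rep.int(seq_along(subs), n_i)
  times <- unlist(lapply(subs, `[[`, "times"), use.names = FALSE)
  conc <- unlist(lapply(subs, `[[`, "concentrations"), use.names = FALSE)
  dose <- rep.int(vapply(subs, `[[`, numeric(1), "dose"), n_i)
  off <- if (isTRUE(spec$dose_offset)) log(dose) else rep.int(0, length(times))
  list(
    y_log = log(conc), conc = conc, times = times, grp = grp,
    n_i = n_i, m = length(subs), N = length(times),
    ids = names(subs),
    X = build_design_matrix(times, spec$powers),
    offset = off
  )
}
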