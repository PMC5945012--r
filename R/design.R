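#' Define a circadian sampling design
#'
#' A study design records the clock times (hours after lights-on) at which
#' samples are collected within one 24-h cycle, and how many replicate animals
#' are collected per time point. Replicates taken on successive days at the
#' same clock time are treated as interchangeable triplicates, so the design
#' has no day axis.
#'
#' @param times Numeric vector of sampling clock-times in hours, strictly
#'   increasing, all within `[0, 24)`.
#' @param replicates_per_time Positive integer, number of replicates collected
#'   at each time point.
#' @param light_on Hour marking light onset (time 0 by convention).
#' @param period Oscillation period in hours; fixed at 24 for this analysis.
#' @return An object of class `study_design`.
#' @seealso [rat_design()] for the default dense 18-point design.
#' @export
#' @examples
#' d <- study_design(times = c(0, 6, 12, 18), replicates_per_time = 2)
#' n_samples(d)
study_design <- function(times, replicates_per_time = 3L, light_on = 0,
                         period = 24) {
  times <- as.numeric(times)
  if (length(times) < 1L || anyNA(times)) {
    stop("`times` must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(times < 0 | times >= 24)) {
    stop("all sampling times must lie in [0, 24)", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  replicates_per_time <- as.integer(replicates_per_time)
  if (is.na(replicates_per_time) || replicates_per_time < 1L) {
    stop("`replicates_per_time` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L || period <= 0) {
    stop("`period` must be a positive number", call. = FALSE)
  }
  structure(
    list(times = times, replicates_per_time = replicates_per_time,
         light_on = light_on, period = period),
    class = "study_design"
  )
}

#' The dense 18-time-point rat sampling design
#'
#' Eighteen unequally spaced time points per 24-h cycle with extra density at
#' the light/dark transitions (lights on at 0 h, off at 12 h), three
#' replicates per time point: 54 samples per tissue. This is the default
#' design of the synthetic generator and of the rhythm-detection examples.
#'
#' @param replicates_per_time Replicates per time point (default 3).
#' @return A `study_design`.
#' @export
rat_design <- function(replicates_per_time = 3L) {
  study_design(
    times = c(0.25, 1, 2, 4, 6, 8, 10, 11, 11.75,
              12.25, 13, 14, 16, 18, 20, 22, 23, 23.75),
    replicates_per_time = replicates_per_time
  )
}

#' Number of samples implied by a design
#' @param design A `study_design`.
#' @return Integer, `length(times) * replicates_per_time`.
#' @export
n_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  length(design$times) * design$replicates_per_time
}

#' Sample metadata table for a design
#'
#' Expands a design into one row per sample, time-major (all replicates of a
#' time point are adjacent), which is the column order the generator uses.
#'
#' @param design A `study_design`.
#' @param tissue Tissue label to attach to every sample.
#' @return A data.frame with columns `sample_id`, `time_h`, `replicate`,
#'   `tissue`.
#' @export
design_samples <- function(design, tissue = "tissue1") {
  stopifnot(inherits(design, "study_design"))
  nt <- length(design$times)
  reps <- design$replicates_per_time
  time_h <- rep(design$times, each = reps)
  replicate <- rep(seq_len(reps), times = nt)
  data.frame(
    sample_id = sprintf("%s_T%05.2f_R%d", tissue, time_h, replicate),
    time_h = time_h,
    replicate = replicate,
    tissue = tissue,
    stringsAsFactors = FALSE
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Circadian study design\n")
  cat("  times (h):", paste(x$times, collapse = ", "), "\n")
  cat("  replicates/time:", x$replicates_per_time,
      " period:", x$period, "h\n")
  invisible(x)
}
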