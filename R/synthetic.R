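#' Simulate trial-like event times
#'
#' Inverse-transform sampling of event times from a parametric survival
#' distribution, with administrative censoring at a fixed horizon (the
#' analogue of end-of-follow-up in a trial readout). For the log-logistic
#' family the quantile is \eqn{t = (u / ((1-u)\lambda))^{1/\gamma}} for
#' uniform \eqn{u}.
#'
#' @param dist A [surv_dist()] truth.
#' @param n Cohort size, \code{>= 1}; default 230 per arm.
#' @param admin_censor Censoring horizon in months, \code{> 0}.
#' @param seed Integer RNG seed; identical seeds give identical cohorts.
#' @return A \code{sim_cohort} data frame with columns \code{time} (months)
#'   and \code{status} (1 event, 0 censored), plus attributes \code{truth},
#'   \code{admin_censor}, \code{seed}.
#' @examples
#' co <- simulate_event_times(surv_dist("loglogistic", 1.92, 0.035),
#'                            n = 100, admin_censor = 36, seed = 1)
#' table(co$status)
#' @export
simulate_event_times <- function(dist, n = 230, admin_censor = 36,
                                 seed = 1) {
  stopifnot_dist(dist)
  if (n < 1) stop("n must be >= 1")
  if (admin_censor <= 0) stop("admin_censor must be > 0")
  set.seed(seed)
  t_raw <- qsurv(dist, stats::runif(n))
  status <- as.integer(t_raw <= admin_censor)
  structure(
    data.frame(time = pmin(t_raw, admin_censor), status = status),
    truth = dist, admin_censor = admin_censor, seed = seed,
    class = c("sim_cohort", "data.frame")
  )
}

#' Kaplan-Meier curve of a simulated cohort
#'
#' Product-limit estimate (via \code{survival::survfit}) returned as a step
#' curve starting at (0, 1).
#'
#' @param cohort A [simulate_event_times()] cohort, or any data frame with
#'   \code{time} and \code{status} columns.
#' @return A \code{km_curve} data frame with columns \code{time} and
#'   \code{survival} (step-function right endpoints), starting at
#'   \code{(0, 1)}.
#' @export
km_curve <- function(cohort) {
  if (!all(c("time", "status") %in% names(cohort)))
    stop("cohort must have 'time' and 'status' columns")
  if (sum(cohort$status) == 0)
    warning("cohort has no events; Kaplan-Meier curve is flat")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = cohort)
  time <- c(0, fit$time)
  surv <- c(1, fit$surv)
  structure(data.frame(time = time, survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Emulate manual digitization of a Kaplan-Meier curve
#'
#' Samples the step function on a time grid, perturbs each reading with
#' Gaussian jitter clipped to \eqn{[0, 1]} (mimicking graph-digitizer
#' error), then restores monotonicity via [digitized_curve()]'s running
#' minimum repair.
#'
#' @param km A [km_curve()] (or any data frame with \code{time},
#'   \code{survival}).
#' @param grid Sampling times in months within the curve support; default
#'   monthly to 36 months.
#' @param jitter_sd Jitter standard deviation in survival-probability
#'   units, \code{>= 0}; default 0.01.
#' @param seed RNG seed for the jitter.
#' @param label,cohort_size Passed to [digitized_curve()].
#' @return A [digitized_curve()].
#' @export
digitize_curve <- function(km, grid = 0:36, jitter_sd = 0.01, seed = 1,
                           label = "digitized", cohort_size = 230) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (any(grid < 0) || any(grid > max(km$time)))
    stop("grid must lie within the curve support [0, ",
         format(max(km$time)), "]")
  step <- stats::stepfun(km$time[-1L], km$survival)
  s <- step(grid)
  if (jitter_sd > 0) {
    set.seed(seed)
    s <- pmin(pmax(s + stats::rnorm(length(s), 0, jitter_sd), 0), 1)
  }
  digitized_curve(grid, s, label = label, cohort_size = cohort_size)
}

#' Export a simulated cohort as CSV
#'
#' @param cohort A \code{sim_cohort}.
#' @param path Output path (columns \code{time_months}, \code{status}).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(
    data.frame(time_months = cohort$time, status = cohort$status),
    path, row.names = FALSE
  )
  invisible(path)
}
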