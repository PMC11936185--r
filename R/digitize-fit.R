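#' Digitized Kaplan-Meier curve
#'
#' Container for survival coordinates read off a published Kaplan-Meier
#' figure (time in months, survival probability). A point at time 0 with
#' survival 1 is inserted if absent, and any survival increases (digitization
#' noise) are repaired to a non-increasing sequence by a running minimum.
#'
#' @param time Strictly increasing times in months, \code{>= 0}.
#' @param survival Survival probabilities in \eqn{[0, 1]}.
#' @param label Curve label (e.g. \code{"tislelizumab OS"}).
#' @param cohort_size Assumed number of patients at risk at time 0, used to
#'   reconstruct pseudo event counts; default 230 (a typical arm size for
#'   this trial setting).
#' @return A \code{digitized_curve}: data frame with columns \code{time},
#'   \code{survival} plus attributes \code{label}, \code{cohort_size} and
#'   \code{repaired} (TRUE when monotonicity repair changed any value).
#' @seealso [interval_counts()], [fit_parametric()], [read_curve()]
#' @export
digitized_curve <- function(time, survival, label = "curve",
                            cohort_size = 230) {
  if (length(time) != length(survival))
    stop("time and survival must have equal length")
  if (any(!is.finite(time)) || any(!is.finite(survival)))
    stop("time and survival must be finite")
  if (any(time < 0)) stop("times must be >= 0")
  if (any(survival < 0 | survival > 1))
    stop("survival values must lie in [0, 1]")
  if (cohort_size < 1 || cohort_size != round(cohort_size))
    stop("cohort_size must be a positive integer")
  o <- order(time)
  time <- time[o]
  survival <- survival[o]
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (time[1L] > 0) {
    time <- c(0, time)
    survival <- c(1, survival)
  } else {
    survival[1L] <- 1
  }
  fixed <- cummin(survival)
  repaired <- any(fixed != survival)
  structure(
    data.frame(time = time, survival = fixed),
    label = label, cohort_size = as.integer(cohort_size),
    repaired = repaired,
    class = c("digitized_curve", "data.frame")
  )
}

#' Read / write a digitized curve as CSV
#'
#' The on-disk dialect is a two-column CSV with header
#' \code{time_months,survival}. Monotonicity repair on read is reported with
#' a message.
#'
#' @param path File path.
#' @param label,cohort_size Passed to [digitized_curve()].
#' @return \code{read_curve}: a \code{digitized_curve};
#'   \code{write_curve}: \code{path}, invisibly.
#' @export
read_curve <- function(path, label = basename(path), cohort_size = 230) {
  d <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(d)))
    stop("curve CSV must have columns 'time_months' and 'survival'")
  cur <- digitized_curve(d$time_months, d$survival, label = label,
                         cohort_size = cohort_size)
  if (isTRUE(attr(cur, "repaired")))
    message("monotonicity repair applied to '", label, "'")
  cur
}

#' @rdname read_curve
#' @param curve A \code{digitized_curve}.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(
    data.frame(time_months = curve$time, survival = curve$survival),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Reconstruct interval event counts from a digitized curve
#'
#' Converts the survival drops between consecutive digitized points into
#' pseudo event counts for an assumed closed cohort with no loss to
#' follow-up before the last point (a simplified Guyot-style reconstruction:
#' the published figure gives no numbers-at-risk, so censoring is assumed
#' administrative at the end of follow-up). At each interval the number of
#' events is \code{round(n_at_risk * (S_i - S_{i+1}) / S_i)}; patients still
#' at risk after the last point are right-censored there.
#'
#' @param curve A [digitized_curve()].
#' @return A data frame with one row per interval: \code{t_start},
#'   \code{t_end}, \code{at_risk}, \code{events}, plus attribute
#'   \code{censored} (count censored at the final time).
#' @examples
#' cur <- digitized_curve(c(0, 6, 12), c(1, 0.5, 0.25), cohort_size = 100)
#' interval_counts(cur)  # 50 and 25 events, 25 censored at 12
#' @export
interval_counts <- function(curve) {
  if (!inherits(curve, "digitized_curve"))
    stop("expected a 'digitized_curve'")
  if (nrow(curve) < 2L)
    stop("curve must contain at least 2 points")
  n0 <- attr(curve, "cohort_size")
  if (n0 < 10) stop("assumed cohort size must be >= 10")
  m <- nrow(curve) - 1L
  at_risk <- events <- integer(m)
  n <- n0
  for (i in seq_len(m)) {
    s_i <- curve$survival[i]
    s_j <- curve$survival[i + 1L]
    d <- if (s_i <= 0) 0L else as.integer(round(n * (s_i - s_j) / s_i))
    d <- min(d, n)
    at_risk[i] <- n
    events[i] <- d
    n <- n - d
  }
  structure(
    data.frame(t_start = curve$time[-nrow(curve)],
               t_end = curve$time[-1L],
               at_risk = at_risk, events = events),
    censored = n,
    class = c("interval_counts", "data.frame")
  )
}

## ---- maximum-likelihood fitting -------------------------------------------

# Heuristic starting values on the log scale, per family, from a regression
# linearisation of S(t) over interior digitized points. Falls back to a
# median-matched default when the regression is degenerate.
fit_start <- function(curve, family) {
  s <- curve$survival
  t <- curve$time
  keep <- t > 0 & s > 1e-6 & s < 1 - 1e-6
  tm <- {
    # first crossing of S = 0.5, linearly interpolated
    below <- which(s <= 0.5)
    if (length(below) == 0L || below[1L] == 1L) max(t) / 2
    else {
      i <- below[1L]
      t[i - 1L] + (t[i] - t[i - 1L]) * (s[i - 1L] - 0.5) /
        (s[i - 1L] - s[i])
    }
  }
  tm <- max(tm, 1e-3)
  reg <- function(y, x) {
    if (sum(keep) >= 2L && stats::sd(x[keep]) > 0)
      stats::coef(stats::lm(y[keep] ~ x[keep]))
    else c(NA_real_, NA_real_)
  }
  switch(family,
    exponential = log(log(2) / tm),
    weibull = {
      co <- reg(log(-log(s)), log(t))
      if (any(!is.finite(co)) || co[2L] <= 0) c(0, log(log(2) / tm))
      else c(log(co[2L]), co[1L])
    },
    loglogistic = {
      co <- reg(log(1 / s - 1), log(t))
      if (any(!is.finite(co)) || co[2L] <= 0) c(0, log(1 / tm))
      else c(log(co[2L]), co[1L])
    },
    lognormal = {
      co <- reg(log(t), stats::qnorm(1 - s))
      if (any(!is.finite(co)) || co[2L] <= 0) c(log(0.8), log(tm))
      else c(log(co[2L]), co[1L])
    },
    gamma = c(0, log(log(2) / tm)),
    gompertz = c(log(0.05), log(log(2) / tm))
  )
}

make_dist <- function(family, par_log) {
  if (family == "exponential")
    surv_dist("exponential", scale = exp(par_log[1L]))
  else
    surv_dist(family, shape = exp(par_log[1L]), scale = exp(par_log[2L]))
}

#' Fit a parametric family to a digitized curve
#'
#' Maximum-likelihood fit of one of the six supported families to the
#' interval-censored pseudo-data reconstructed by [interval_counts()]. The
#' likelihood is multinomial over the digitized intervals,
#' \deqn{\ell = \sum_i d_i \log\{S(t_i) - S(t_{i+1})\} + c \log S(t_m),}
#' with \eqn{d_i} the reconstructed event counts and \eqn{c} the count
#' right-censored at the last point. Parameters are optimised on the log
#' scale (Nelder-Mead; Brent for the one-parameter exponential) from
#' regression-based starting values. Non-convergence is reported via the
#' \code{converged} flag, never silently replaced.
#'
#' @param curve A [digitized_curve()] with at least 3 points spanning a
#'   survival drop.
#' @param family A family name as in [surv_dist()], or \code{"all"} to fit
#'   every family and return a list.
#' @return A \code{surv_fit} object: list with elements \code{distribution}
#'   ([surv_dist()]), \code{log_likelihood}, \code{aic}, \code{bic},
#'   \code{n_params}, \code{n_effective} (assumed cohort size),
#'   \code{converged}, \code{label}. For \code{family = "all"}, a named list
#'   of \code{surv_fit}s.
#' @examples
#' truth <- surv_dist("loglogistic", 1.92, 0.035)
#' cur <- digitized_curve(0:24, psurv(truth, 0:24), cohort_size = 5000)
#' fit <- fit_parametric(cur, "loglogistic")
#' fit$distribution
#' @export
fit_parametric <- function(curve, family = "all") {
  if (!inherits(curve, "digitized_curve"))
    stop("expected a 'digitized_curve'")
  families <- c("exponential", "weibull", "gompertz", "gamma",
                "lognormal", "loglogistic")
  if (identical(family, "all")) {
    fits <- lapply(families, function(f) fit_parametric(curve, f))
    names(fits) <- families
    return(fits)
  }
  family <- match.arg(family, families)
  if (nrow(curve) < 3L)
    stop("curve must contain at least 3 points for fitting")
  if (min(curve$survival) >= 1)
    stop("curve must span at least one survival drop")
  counts <- interval_counts(curve)
  cens <- attr(counts, "censored")
  t_end <- counts$t_end
  d <- counts$events
  t_last <- t_end[length(t_end)]
  n_eff <- attr(curve, "cohort_size")

  negll <- function(par_log) {
    dist <- tryCatch(make_dist(family, par_log), error = function(e) NULL)
    if (is.null(dist)) return(1e10)
    s <- psurv(dist, c(0, t_end))
    p_int <- pmax(s[-length(s)] - s[-1L], 1e-300)
    ll <- sum(d * log(p_int)) + cens * log(max(s[length(s)], 1e-300))
    if (!is.finite(ll)) 1e10 else -ll
  }

  start <- fit_start(curve, family)
  npar <- length(start)
  fail <- function() {
    structure(list(distribution = NULL, log_likelihood = NA_real_,
                   aic = NA_real_, bic = NA_real_, n_params = npar,
                   n_effective = n_eff, converged = FALSE,
                   family = family, label = attr(curve, "label")),
              class = "surv_fit")
  }
  opt <- tryCatch({
    if (npar == 1L)
      stats::optim(start, negll, method = "Brent", lower = -25, upper = 10)
    else
      stats::optim(start, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
  }, error = function(e) NULL)
  if (is.null(opt) || opt$value >= 1e9) return(fail())
  converged <- is.null(opt$convergence) || opt$convergence == 0
  ll <- -opt$value
  structure(
    list(distribution = make_dist(family, opt$par),
         log_likelihood = ll,
         aic = 2 * npar - 2 * ll,
         bic = npar * log(n_eff) - 2 * ll,
         n_params = npar, n_effective = n_eff,
         converged = converged, family = family,
         label = attr(curve, "label")),
    class = "surv_fit"
  )
}

#' @export
print.surv_fit <- function(x, ...) {
  cat("Parametric fit (", x$family, ") to '", x$label, "'\n", sep = "")
  if (!x$converged) cat("  ** optimizer did not converge **\n")
  if (!is.null(x$distribution))
    cat("  shape:", format(x$distribution$shape),
        " scale:", format(x$distribution$scale), "\n")
  cat("  logLik:", format(x$log_likelihood),
      " AIC:", format(x$aic), " BIC:", format(x$bic), "\n")
  invisible(x)
}

#' @export
logLik.surv_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params,
            nobs = object$n_effective, class = "logLik")
}

#' Select the best-fitting distribution
#'
#' Minimum-AIC selection over a list of fits, with ties broken by minimum
#' BIC and then by fewest parameters; non-converged fits are excluded. The
#' full ranking is retained as attribute \code{ranking} (a data frame with
#' one row per family) for reporting.
#'
#' @param fits A list of \code{surv_fit} objects, e.g. from
#'   \code{fit_parametric(curve, "all")}.
#' @return The selected \code{surv_fit}, with attribute \code{ranking}.
#' @export
select_distribution <- function(fits) {
  if (inherits(fits, "surv_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic),
               logical(1L))
  if (!any(ok)) stop("no converged fits to select from")
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1L), "family"),
    logLik = vapply(fits, `[[`, numeric(1L), "log_likelihood"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    bic = vapply(fits, `[[`, numeric(1L), "bic"),
    n_params = vapply(fits, `[[`, numeric(1L), "n_params"),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1L))
  )
  cand <- which(ok)
  o <- cand[order(tab$aic[cand], tab$bic[cand], tab$n_params[cand])]
  best <- fits[[o[1L]]]
  attr(best, "ranking") <- tab[order(!tab$converged, tab$aic, tab$bic,
                                     tab$n_params), ]
  best
}

#' Write a fit-comparison report
#'
#' One row per fitted family: family, shape, scale, logLik, AIC, BIC and a
#' convergence flag.
#'
#' @param fits A list of \code{surv_fit}s.
#' @param path CSV output path.
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    data.frame(
      family = f$family,
      shape = if (is.null(f$distribution)) NA_real_ else f$distribution$shape,
      scale = if (is.null(f$distribution)) NA_real_ else f$distribution$scale,
      logLik = f$log_likelihood, aic = f$aic, bic = f$bic,
      converged = isTRUE(f$converged)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
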