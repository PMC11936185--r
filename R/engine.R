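as_surv_dist <- function(spec) {
  if (inherits(spec, "surv_dist")) return(spec)
  if (spec$family == "exponential")
    surv_dist("exponential", scale = spec$scale)
  else
    surv_dist(spec$family, shape = spec$shape, scale = spec$scale)
}

#' Number of model cycles
#'
#' Cycles needed to cover the time horizon:
#' \code{ceiling(horizon_in_days / cycle_days)} (174 for 10 years of 21-day
#' cycles).
#'
#' @param deck A parameter deck.
#' @return Integer cycle count.
#' @export
n_cycles <- function(deck) {
  st <- deck$settings
  as.integer(ceiling(st$horizon_years * st$days_per_year / st$cycle_days))
}

#' Per-cycle discount factor
#'
#' Compound discounting at the annual rate, applied at each cycle start:
#' \code{(1 + rate)^(-k * cycle_days / 365.25)}; cycle 0 has factor 1.
#'
#' @param cycle_index Cycle index (0-based), \code{>= 0}; vectorised.
#' @param deck A parameter deck (supplies rate and cycle length).
#' @return Discount factor(s) in \eqn{(0, 1]}.
#' @examples
#' discount_factor(18, base_deck())  # ~0.9508
#' @export
discount_factor <- function(cycle_index, deck) {
  if (any(cycle_index < 0)) stop("cycle_index must be >= 0")
  st <- deck$settings
  (1 + st$discount_rate)^(-cycle_index * st$cycle_days / st$days_per_year)
}

#' Build the discounted cohort trace for one arm
#'
#' Evaluates partitioned-survival state occupancy on the cycle grid over the
#' full horizon. Row \code{k} (0-based cycle index) carries occupancy at the
#' cycle start, or at the cycle midpoint when
#' \code{deck$settings$half_cycle} is \code{TRUE} (a half-cycle correction).
#' The newly-progressed fraction is the per-cycle increase of
#' \eqn{1 - S_{PFS}} floored at zero (progression events irrespective of
#' subsequent death), which prices one-time costs incurred at progression.
#'
#' @param deck A parameter deck.
#' @param arm Arm name.
#' @return A \code{cohort_trace} data frame with one row per cycle and
#'   columns \code{cycle}, \code{time_months}, \code{pf}, \code{pd},
#'   \code{dead}, \code{discount}, \code{new_pd}.
#' @export
build_trace <- function(deck, arm = arm_names()) {
  arm <- match.arg(arm)
  st <- deck$settings
  nk <- n_cycles(deck)
  if (nk < 1) stop("horizon must cover at least one cycle")
  k <- 0:(nk - 1L)
  cycle_months <- st$cycle_days / (st$days_per_year / 12)
  offset <- if (isTRUE(st$half_cycle)) 0.5 else 0
  t_eval <- (k + offset) * cycle_months
  pfs <- as_surv_dist(deck$survival[[arm]]$pfs)
  os <- as_surv_dist(deck$survival[[arm]]$os)
  occ <- state_occupancy(pfs, os, t_eval)
  s_pfs <- pmin(psurv(pfs, t_eval), psurv(os, t_eval))
  new_pd <- pmax(-diff(c(if (offset > 0) min(psurv(pfs, 0), psurv(os, 0))
                         else s_pfs[1L], s_pfs)), 0)
  structure(
    data.frame(cycle = k, time_months = t_eval,
               pf = occ$pf, pd = occ$pd, dead = occ$dead,
               discount = discount_factor(k, deck),
               new_pd = new_pd),
    arm = arm, class = c("cohort_trace", "data.frame")
  )
}

#' Accrue discounted costs over a trace
#'
#' Cost accrual per cycle, all multiplied by the cycle's discount factor:
#' drug acquisition while progression-free (induction deck during the
#' induction window, maintenance deck afterwards, subject to the optional
#' \code{max_treatment_cycles} cap); follow-up, laboratory and CT
#' monitoring while progression-free; best supportive care while
#' progressed-alive; a one-time subsequent-treatment cost weighted by the
#' arm's uptake and the newly-progressed fraction. The adverse-event burden
#' is charged once, undiscounted, at model entry.
#'
#' Per-cycle cost inputs are interpreted per \emph{dosing} cycle
#' (\code{settings$cost_cycle_days}, 21 days); when the model step
#' \code{settings$cycle_days} differs, per-cycle accruals are rescaled by
#' \code{cycle_days / cost_cycle_days} so the cycle length is a pure
#' discretization choice. Induction and treatment-cap windows are likewise
#' defined in dosing cycles.
#'
#' @param trace A [build_trace()] result for the same deck and arm.
#' @param deck A parameter deck.
#' @param arm Arm name.
#' @return A list: \code{total} (USD) and \code{breakdown} (named vector:
#'   drug, followup, labs, ct, bsc, subsequent, ae). The breakdown sums to
#'   the total.
#' @export
accrue_costs <- function(trace, deck, arm = arm_names()) {
  arm <- match.arg(arm)
  st <- deck$settings
  ind <- cycle_drug_cost(deck, arm, "induction")
  mnt <- cycle_drug_cost(deck, arm, "maintenance")
  k <- trace$cycle
  scale <- st$cycle_days / st$cost_cycle_days
  day <- k * st$cycle_days  # day at cycle start
  on_treat <- day < st$max_treatment_cycles * st$cost_cycle_days
  in_induction <- day < deck$regimen$induction_cycles * st$cost_cycle_days
  drug_cycle <- ifelse(in_induction, ind, mnt) * on_treat * scale
  w_pf <- trace$pf * trace$discount
  w_pd <- trace$pd * trace$discount
  care <- deck$care
  ae <- ae_burden(deck, arm)
  breakdown <- c(
    drug = sum(drug_cycle * w_pf),
    followup = care$followup * scale * sum(w_pf),
    labs = care$labs * scale * sum(w_pf),
    ct = care$ct * scale * sum(w_pf),
    bsc = care$bsc * scale * sum(w_pd),
    subsequent = deck$subsequent$cost * deck$subsequent$uptake[[arm]] *
      sum(trace$new_pd * trace$discount),
    ae = ae$cost
  )
  total <- sum(breakdown)
  if (abs(total - sum(breakdown)) > 1e-6)
    stop("internal cost breakdown inconsistency")
  list(total = total, breakdown = breakdown)
}

#' Accrue discounted QALYs over a trace
#'
#' \deqn{QALY = \sum_k (pf_k u_{PF} + pd_k u_{PD})\, \Delta t\, d_k -
#'   \text{AE QALY loss},}
#' with \eqn{\Delta t} the cycle length in years and \eqn{d_k} the discount
#' factor.
#'
#' @param trace A [build_trace()] result.
#' @param deck A parameter deck.
#' @param arm Arm name.
#' @return Total discounted QALYs (scalar).
#' @export
accrue_qalys <- function(trace, deck, arm = arm_names()) {
  arm <- match.arg(arm)
  u <- deck$utilities
  if (u$pf < 0 || u$pf > 1 || u$pd < 0 || u$pd > 1)
    stop("utilities must lie in [0, 1]")
  cycle_years <- deck$settings$cycle_days / deck$settings$days_per_year
  ae <- ae_burden(deck, arm)
  sum((trace$pf * u$pf + trace$pd * u$pd) * cycle_years * trace$discount) -
    ae$qaly_loss
}

#' Run one model arm
#'
#' Builds the cohort trace and accrues discounted costs and QALYs plus
#' undiscounted life-years. Deterministic: identical inputs give identical
#' outputs.
#'
#' @param deck A parameter deck.
#' @param arm Arm name.
#' @param keep_trace Attach the trace to the result?
#' @return An \code{arm_result}: list with \code{arm}, \code{cost},
#'   \code{qalys}, \code{life_years}, \code{breakdown} and (optionally)
#'   \code{trace}.
#' @export
run_arm <- function(deck, arm = arm_names(), keep_trace = FALSE) {
  arm <- match.arg(arm)
  trace <- build_trace(deck, arm)
  costs <- accrue_costs(trace, deck, arm)
  cycle_years <- deck$settings$cycle_days / deck$settings$days_per_year
  out <- list(
    arm = arm,
    cost = costs$total,
    qalys = accrue_qalys(trace, deck, arm),
    life_years = sum((trace$pf + trace$pd) * cycle_years),
    breakdown = costs$breakdown
  )
  if (keep_trace) out$trace <- trace
  class(out) <- "arm_result"
  out
}

#' @export
print.arm_result <- function(x, ...) {
  cat("Arm:", x$arm, "\n")
  cat("  discounted cost:  $", formatC(x$cost, format = "f", digits = 2),
      "\n", sep = "")
  cat("  discounted QALYs: ", formatC(x$qalys, format = "f", digits = 4),
      "\n", sep = "")
  cat("  life-years (undiscounted): ",
      formatC(x$life_years, format = "f", digits = 4), "\n", sep = "")
  cat("  cost breakdown:\n")
  for (nm in names(x$breakdown))
    cat(sprintf("    %-11s $%12.2f\n", nm, x$breakdown[[nm]]))
  invisible(x)
}

#' Run the full base-case cost-effectiveness analysis
#'
#' The central model function: runs both arms of the partitioned-survival
#' model on a parameter deck and compares them incrementally (tislelizumab
#' plus chemotherapy vs chemotherapy alone).
#'
#' @param deck A parameter deck; defaults to [base_deck()].
#' @param keep_traces Attach per-arm cohort traces?
#' @return A \code{cea_result}: list with \code{arms} (two
#'   \code{arm_result}s), \code{incremental} (a [incremental_analysis()]
#'   result) and \code{wtp}.
#' @examples
#' res <- run_cea(base_deck())
#' res
#' @export
run_cea <- function(deck = base_deck(), keep_traces = FALSE) {
  arms <- lapply(arm_names(), run_arm, deck = deck,
                 keep_trace = keep_traces)
  names(arms) <- arm_names()
  inc <- incremental_analysis(arms$tislelizumab, arms$chemotherapy,
                              wtp = deck$settings$wtp)
  structure(list(arms = arms, incremental = inc,
                 wtp = deck$settings$wtp),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  inc <- x$incremental
  cat("Partitioned-survival cost-effectiveness analysis\n\n")
  cat(sprintf("  %-22s %14s %10s\n", "Group", "Cost ($)", "QALYs"))
  for (a in x$arms)
    cat(sprintf("  %-22s %14s %10.4f\n", a$arm,
                formatC(a$cost, format = "f", digits = 2, big.mark = ","),
                a$qalys))
  cat("\n")
  cat("  Incremental cost:  $",
      formatC(inc$d_cost, format = "f", digits = 2, big.mark = ","),
      "\n", sep = "")
  cat("  Incremental QALYs: ",
      formatC(inc$d_qaly, format = "f", digits = 4), "\n", sep = "")
  cat("  ICER:              ", inc$icer_label, "\n", sep = "")
  cat("  NMB at WTP $",
      formatC(x$wtp, format = "f", digits = 2, big.mark = ","), ": $",
      formatC(inc$nmb, format = "f", digits = 2, big.mark = ","),
      "\n", sep = "")
  cat("  Cost-effective at WTP: ",
      if (inc$cost_effective) "yes" else "no", "\n", sep = "")
  invisible(x)
}

#' @export
summary.cea_result <- function(object, ...) {
  inc <- object$incremental
  data.frame(
    group = c(vapply(object$arms, `[[`, character(1L), "arm"),
              "incremental"),
    cost = c(vapply(object$arms, `[[`, numeric(1L), "cost"), inc$d_cost),
    qalys = c(vapply(object$arms, `[[`, numeric(1L), "qalys"), inc$d_qaly),
    icer = c(NA_real_, NA_real_,
             if (is.na(inc$icer)) NA_real_ else inc$icer)
  )
}

#' Export a cohort trace as CSV
#'
#' @param trace A [build_trace()] result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
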