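#' Net monetary benefit
#'
#' \code{NMB = wtp * dqaly - dcost}; non-negative exactly when the
#' intervention is cost-effective at that willingness-to-pay.
#'
#' @param dcost Incremental cost (USD); vectorised.
#' @param dqaly Incremental QALYs; vectorised.
#' @param wtp Willingness-to-pay per QALY, \code{>= 0}.
#' @return NMB in USD.
#' @examples
#' net_monetary_benefit(43938.07, 2.21, 39855.79)
#' @export
net_monetary_benefit <- function(dcost, dqaly, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * dqaly - dcost
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental cost and QALYs (intervention minus comparator), the
#' ICER, net monetary benefit at the willingness-to-pay threshold and the
#' cost-effectiveness decision. Dominance quadrants are labelled rather than
#' reported as (meaningless) negative ratios: \code{"dominant"} when the
#' intervention saves money and gains QALYs, \code{"dominated"} when it
#' costs more and loses QALYs. A zero QALY difference yields an
#' undefined-ICER label, not a division error. The decision satisfies
#' \code{cost_effective == (NMB >= 0)} in every quadrant.
#'
#' @param intervention,comparator \code{arm_result} objects from
#'   [run_arm()], or lists with \code{cost} and \code{qalys}.
#' @param wtp Willingness-to-pay per QALY.
#' @return A \code{ce_result}: list with \code{d_cost}, \code{d_qaly},
#'   \code{icer} (numeric, \code{NA} in dominance/undefined cases),
#'   \code{icer_label}, \code{nmb}, \code{cost_effective}, plus the per-arm
#'   totals.
#' @export
incremental_analysis <- function(intervention, comparator, wtp) {
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qalys - comparator$qalys
  nmb <- net_monetary_benefit(d_cost, d_qaly, wtp)
  eps <- 0
  if (d_qaly > eps && d_cost < 0) {
    icer <- NA_real_
    label <- "dominant"
  } else if (d_qaly < 0 && d_cost > 0) {
    icer <- NA_real_
    label <- "dominated"
  } else if (d_qaly == 0) {
    icer <- NA_real_
    label <- if (d_cost == 0) "undefined (no difference)"
             else "undefined (equal QALYs)"
  } else {
    icer <- d_cost / d_qaly
    label <- paste0("$", formatC(icer, format = "f", digits = 2,
                                 big.mark = ","), " per QALY")
  }
  structure(
    list(
      intervention = intervention$arm %||% "intervention",
      comparator = comparator$arm %||% "comparator",
      cost = c(intervention = intervention$cost,
               comparator = comparator$cost),
      qalys = c(intervention = intervention$qalys,
                comparator = comparator$qalys),
      d_cost = d_cost, d_qaly = d_qaly,
      icer = icer, icer_label = label,
      wtp = wtp, nmb = nmb,
      cost_effective = nmb >= 0
    ),
    class = "ce_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ce_result <- function(x, ...) {
  cat("Incremental analysis: ", x$intervention, " vs ", x$comparator,
      "\n", sep = "")
  cat("  d_cost: $", formatC(x$d_cost, format = "f", digits = 2,
                             big.mark = ","), "\n", sep = "")
  cat("  d_QALY: ", formatC(x$d_qaly, format = "f", digits = 4),
      "\n", sep = "")
  cat("  ICER:   ", x$icer_label, "\n", sep = "")
  cat("  NMB:    $", formatC(x$nmb, format = "f", digits = 2,
                             big.mark = ","),
      "  (cost-effective: ", if (x$cost_effective) "yes" else "no", ")\n",
      sep = "")
  invisible(x)
}

#' Export an incremental result as CSV
#'
#' Single-row CSV mirroring the base-case table layout (per-arm cost and
#' QALYs, incremental cost/QALY, ICER) plus NMB and the decision.
#'
#' @param ce A \code{ce_result}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ce_result <- function(ce, path) {
  utils::write.csv(data.frame(
    intervention = ce$intervention,
    comparator = ce$comparator,
    cost_intervention = ce$cost[["intervention"]],
    cost_comparator = ce$cost[["comparator"]],
    qalys_intervention = ce$qalys[["intervention"]],
    qalys_comparator = ce$qalys[["comparator"]],
    d_cost = ce$d_cost, d_qaly = ce$d_qaly,
    icer = ce$icer, icer_label = ce$icer_label,
    wtp = ce$wtp, nmb = ce$nmb,
    cost_effective = ce$cost_effective
  ), path, row.names = FALSE)
  invisible(path)
}
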