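#' Partitioned-survival state occupancy
#'
#' Converts a pair of progression-free-survival and overall-survival curves
#' into three-state occupancy at time \code{t}: progression-free (PF),
#' progressed-alive (PD) and dead. The partitioned-survival reading is
#' \deqn{PF = \min(S_{PFS}, S_{OS}),\quad dead = 1 - S_{OS},\quad
#'       PD = S_{OS} - PF.}
#' Clipping PF at \eqn{S_{OS}} resolves crossings where an extrapolated PFS
#' curve exceeds OS; the three fractions always sum to one.
#'
#' @param pfs,os [surv_dist()] objects for progression-free and overall
#'   survival.
#' @param t Time(s) in months.
#' @return A data frame with columns \code{pf}, \code{pd}, \code{dead}, one
#'   row per element of \code{t}.
#' @examples
#' os  <- surv_dist("loglogistic", 1.78, 0.0068)
#' pfs <- surv_dist("loglogistic", 1.92, 0.035)
#' state_occupancy(pfs, os, c(0, 12))
#' @export
state_occupancy <- function(pfs, os, t) {
  s_pfs <- psurv(pfs, t)
  s_os <- psurv(os, t)
  pf <- pmin(s_pfs, s_os)
  pd <- pmax(s_os - pf, 0)
  data.frame(pf = pf, pd = pd, dead = 1 - s_os)
}
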