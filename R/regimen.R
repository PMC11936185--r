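#' Body-surface-area dose
#'
#' Dose in mg for a drug prescribed per square metre of body surface area.
#'
#' @param dose_per_m2 Dose in mg/m^2, \code{>= 0}.
#' @param bsa_m2 Body surface area in m^2, \code{> 0}.
#' @return Dose in mg.
#' @examples
#' bsa_dose(100, 1.72)  # 172 mg etoposide per day
#' @export
bsa_dose <- function(dose_per_m2, bsa_m2) {
  if (any(dose_per_m2 < 0)) stop("dose_per_m2 must be >= 0")
  if (any(bsa_m2 <= 0)) stop("body surface area must be > 0")
  dose_per_m2 * bsa_m2
}

#' Calvert carboplatin dose
#'
#' Carboplatin dose (mg) from the Calvert formula,
#' \code{dose = AUC x (GFR + 25)}, with the target area-under-curve in
#' mg.min/mL and the glomerular filtration rate in mL/min.
#'
#' @param auc_target Target AUC, \code{>= 0}.
#' @param gfr_ml_min Renal function in mL/min, \code{>= 0}.
#' @return Dose in mg.
#' @examples
#' calvert_dose(5, 70)  # 475 mg
#' @export
calvert_dose <- function(auc_target, gfr_ml_min) {
  if (any(auc_target < 0)) stop("auc_target must be >= 0")
  if (any(gfr_ml_min < 0)) stop("gfr must be >= 0")
  auc_target * (gfr_ml_min + 25)
}

#' Per-cycle drug acquisition cost
#'
#' Expected drug cost of one 21-day cycle for an arm and treatment phase.
#' Induction combines etoposide (100 mg/m^2 on days 1-3), a platinum agent
#' (cisplatin 75 mg/m^2 or carboplatin at AUC 5, weighted by the cisplatin
#' fraction) and, in the tislelizumab arm, a flat 200 mg dose of
#' tislelizumab. Maintenance is tislelizumab alone in that arm and nothing
#' in the chemotherapy arm. Costs are linear in the per-mg unit prices (no
#' vial rounding).
#'
#' @param deck A parameter deck ([base_deck()]).
#' @param arm \code{"tislelizumab"} or \code{"chemotherapy"}.
#' @param phase \code{"induction"} or \code{"maintenance"}.
#' @return Cost in USD for one cycle.
#' @examples
#' cycle_drug_cost(base_deck(), "tislelizumab", "induction")    # ~622.82
#' cycle_drug_cost(base_deck(), "tislelizumab", "maintenance")  # 356.00
#' @export
cycle_drug_cost <- function(deck, arm = arm_names(),
                            phase = c("induction", "maintenance")) {
  arm <- match.arg(arm)
  phase <- match.arg(phase)
  pr <- deck$prices
  rg <- deck$regimen
  needed <- if (phase == "induction")
    c("etoposide", "cisplatin", "carboplatin",
      if (arm == "tislelizumab") "tislelizumab")
  else if (arm == "tislelizumab") "tislelizumab" else character(0)
  missing_p <- setdiff(needed, names(pr))
  if (length(missing_p))
    stop("missing drug price(s): ", paste(missing_p, collapse = ", "))
  tis <- rg$tislelizumab_mg * pr$tislelizumab
  if (phase == "maintenance")
    return(if (arm == "tislelizumab") tis else 0)
  etop <- bsa_dose(rg$etoposide_mg_m2, deck$patient$bsa_m2) *
    rg$etoposide_days * pr$etoposide
  cis <- bsa_dose(rg$cisplatin_mg_m2, deck$patient$bsa_m2) * pr$cisplatin
  carb <- calvert_dose(rg$carboplatin_auc, deck$patient$gfr_ml_min) *
    pr$carboplatin
  plat <- rg$cisplatin_fraction * cis + (1 - rg$cisplatin_fraction) * carb
  etop + plat + (if (arm == "tislelizumab") tis else 0)
}

#' One-time adverse-event burden
#'
#' Expected cost and QALY loss from grade >= 3 adverse events, applied once
#' per patient at model entry: cost is the incidence-weighted sum of
#' per-event management costs; the QALY loss applies each event's
#' disutility for one cycle's duration.
#'
#' @param deck A parameter deck.
#' @param arm Arm name.
#' @return A list with elements \code{cost} (USD) and \code{qaly_loss}.
#' @examples
#' ae_burden(base_deck(), "tislelizumab")$cost  # ~383.23
#' @export
ae_burden <- function(deck, arm = arm_names()) {
  arm <- match.arg(arm)
  inc <- unlist(deck$ae$incidence[[arm]])
  events <- names(inc)
  cost <- unlist(deck$ae$costs)[events]
  disu <- unlist(deck$ae$disutilities)[events]
  if (any(is.na(cost)) || any(is.na(disu)))
    stop("adverse-event costs/disutilities missing for: ",
         paste(events[is.na(cost) | is.na(disu)], collapse = ", "))
  cycle_years <- deck$settings$cost_cycle_days / deck$settings$days_per_year
  list(cost = sum(inc * cost),
       qaly_loss = sum(inc * disu) * cycle_years)
}
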