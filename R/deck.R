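#' The base-case parameter deck
#'
#' Returns the complete model input deck: log-logistic survival parameters
#' for both arms' PFS and OS curves, drug unit prices, dosing rules, adverse
#' event incidences/costs/disutilities, routine-care costs, utilities,
#' subsequent-treatment inputs and global settings (21-day cycle, 10-year
#' horizon, 5\% annual discount, willingness-to-pay $39,855.79/QALY).
#' All monetary values are 2023 US dollars (converted from RMB at
#' 7.05 RMB/USD); times are months.
#'
#' @return A nested list of class \code{cea_deck}.
#' @examples
#' deck <- base_deck()
#' deck$survival$tislelizumab$os$shape
#' @seealso [read_deck()], [validate_deck()], [param_specs()], [run_cea()]
#' @export
base_deck <- function() {
  deck <- list(
    settings = list(
      cycle_days = 21,
      cost_cycle_days = 21,  # cycle length the per-cycle cost inputs refer to
      horizon_years = 10,
      days_per_year = 365.25,
      discount_rate = 0.05,
      wtp = 39855.79,
      half_cycle = FALSE,
      max_treatment_cycles = Inf,
      currency = "USD",
      rmb_per_usd = 7.05  # provenance of the currency conversion only
    ),
    survival = list(
      tislelizumab = list(
        os  = list(family = "loglogistic", shape = 1.78, scale = 0.0068),
        pfs = list(family = "loglogistic", shape = 1.92, scale = 0.035)
      ),
      chemotherapy = list(
        os  = list(family = "loglogistic", shape = 2.37, scale = 0.0019),
        pfs = list(family = "loglogistic", shape = 3.97, scale = 0.0022)
      )
    ),
    patient = list(
      body_weight_kg = 60,   # carried for completeness; no dosing rule uses it
      bsa_m2 = 1.72,
      gfr_ml_min = 70
    ),
    prices = list(  # USD per mg
      tislelizumab = 1.78,
      etoposide = 0.45,
      cisplatin = 0.22,
      carboplatin = 0.086
    ),
    regimen = list(
      induction_cycles = 4,
      tislelizumab_mg = 200,
      etoposide_mg_m2 = 100,
      etoposide_days = 3,
      cisplatin_mg_m2 = 75,
      carboplatin_auc = 5,
      cisplatin_fraction = 0.5
    ),
    ae = list(
      costs = list(  # management cost per event, USD
        anaemia = 531.72, leukopenia = 461.25,
        neutropenia = 84.21, thrombocytopenia = 1054.00
      ),
      disutilities = list(
        anaemia = 0.073, leukopenia = 0.20,
        neutropenia = 0.2, thrombocytopenia = 0.19
      ),
      incidence = list(
        tislelizumab = list(
          anaemia = 0.16, leukopenia = 0.11,
          neutropenia = 0.56, thrombocytopenia = 0.19
        ),
        chemotherapy = list(
          anaemia = 0.17, leukopenia = 0.10,
          neutropenia = 0.55, thrombocytopenia = 0.25
        )
      )
    ),
    care = list(  # USD per cycle
      followup = 55.60,
      labs = 92.50,
      ct = 105.90,
      bsc = 359.52
    ),
    subsequent = list(
      cost = 854.05,  # one-time at progression
      uptake = list(tislelizumab = 0.60, chemotherapy = 0.74)
    ),
    utilities = list(pf = 0.67, pd = 0.47)
  )
  class(deck) <- c("cea_deck", "list")
  deck
}

arm_names <- function() c("tislelizumab", "chemotherapy")

ae_events <- function()
  c("anaemia", "leukopenia", "neutropenia", "thrombocytopenia")

#' Get or set a deck value by dotted path
#'
#' Parameters are addressed by dotted paths into the nested deck, e.g.
#' \code{"prices.tislelizumab"} or
#' \code{"ae.incidence.chemotherapy.anaemia"}. These names are the handles
#' used by the sensitivity-analysis machinery.
#'
#' @param deck A [base_deck()]-shaped deck.
#' @param name Dotted path.
#' @param value Replacement value (for \code{set_param}).
#' @return \code{get_param}: the value; \code{set_param}: the modified deck.
#' @examples
#' d <- set_param(base_deck(), "utilities.pf", 0.5)
#' get_param(d, "utilities.pf")
#' @export
get_param <- function(deck, name) {
  path <- strsplit(name, ".", fixed = TRUE)[[1L]]
  node <- deck
  for (p in path) {
    if (is.null(node[[p]]))
      stop("unknown parameter '", name, "'")
    node <- node[[p]]
  }
  node
}

#' @rdname get_param
#' @export
set_param <- function(deck, name, value) {
  get_param(deck, name)  # errors on unknown names
  deck[[strsplit(name, ".", fixed = TRUE)[[1L]]]] <- value
  deck
}

#' Sensitivity-analysis parameter specifications
#'
#' Builds the table of parameters varied in one-way and probabilistic
#' sensitivity analyses: every cost, utility, disutility, adverse-event
#' incidence, the body surface area, the discount rate and the cisplatin
#' fraction. Ranges are the published minimum/maximum where printed
#' (+/-25\% of base for costs and utilities; 0.04-0.06 for the discount
#' rate) and a constructed +/-25\% band where the source prints none
#' (adverse-event incidences; the cisplatin fraction uses 0.25-0.75).
#' Costs carry a gamma PSA family, probabilities and utilities a beta
#' family. Survival shape/scale parameters are deliberately absent: no
#' distribution is published for them, so they are held fixed in the PSA.
#'
#' @param deck A parameter deck.
#' @return A data frame with columns \code{name}, \code{base}, \code{low},
#'   \code{high}, \code{dist} (\code{"gamma"}, \code{"beta"} or
#'   \code{"fixed"}) and \code{role}.
#' @export
param_specs <- function(deck) {
  row <- function(name, low, high, dist, role)
    data.frame(name = name, base = get_param(deck, name),
               low = low, high = high, dist = dist, role = role)
  pm25 <- function(name, dist, role) {
    b <- get_param(deck, name)
    row(name, 0.75 * b, 1.25 * b, dist, role)
  }
  specs <- rbind(
    row("prices.tislelizumab", 1.34, 2.23, "gamma", "cost"),
    row("prices.etoposide", 0.34, 0.56, "gamma", "cost"),
    row("prices.cisplatin", 0.17, 0.28, "gamma", "cost"),
    row("prices.carboplatin", 0.06, 0.11, "gamma", "cost"),
    row("ae.costs.anaemia", 398.79, 664.65, "gamma", "cost"),
    row("ae.costs.leukopenia", 345.94, 576.56, "gamma", "cost"),
    row("ae.costs.neutropenia", 63.16, 105.26, "gamma", "cost"),
    row("ae.costs.thrombocytopenia", 790.50, 1317.50, "gamma", "cost"),
    row("subsequent.cost", 640.54, 1067.56, "gamma", "cost"),
    row("care.bsc", 269.64, 449.40, "gamma", "cost"),
    row("care.followup", 41.70, 69.50, "gamma", "cost"),
    row("care.labs", 69.38, 115.63, "gamma", "cost"),
    row("care.ct", 79.43, 132.38, "gamma", "cost"),
    row("utilities.pf", 0.50, 0.84, "beta", "utility"),
    row("utilities.pd", 0.35, 0.59, "beta", "utility"),
    row("ae.disutilities.anaemia", 0.05, 0.09, "beta", "utility"),
    row("ae.disutilities.neutropenia", 0.15, 0.25, "beta", "utility"),
    row("ae.disutilities.thrombocytopenia", 0.14, 0.24, "beta", "utility"),
    row("ae.disutilities.leukopenia", 0.15, 0.25, "beta", "utility"),
    row("patient.bsa_m2", 1.29, 2.15, "beta", "structural"),
    row("settings.discount_rate", 0.04, 0.06, "beta", "structural"),
    row("regimen.cisplatin_fraction", 0.25, 0.75, "beta", "probability"),
    pm25("ae.incidence.tislelizumab.anaemia", "beta", "incidence"),
    pm25("ae.incidence.tislelizumab.leukopenia", "beta", "incidence"),
    pm25("ae.incidence.tislelizumab.neutropenia", "beta", "incidence"),
    pm25("ae.incidence.tislelizumab.thrombocytopenia", "beta", "incidence"),
    pm25("ae.incidence.chemotherapy.anaemia", "beta", "incidence"),
    pm25("ae.incidence.chemotherapy.leukopenia", "beta", "incidence"),
    pm25("ae.incidence.chemotherapy.neutropenia", "beta", "incidence"),
    pm25("ae.incidence.chemotherapy.thrombocytopenia", "beta", "incidence"),
    pm25("subsequent.uptake.tislelizumab", "beta", "probability"),
    pm25("subsequent.uptake.chemotherapy", "beta", "probability")
  )
  rownames(specs) <- NULL
  specs
}

## ---- validation ------------------------------------------------------------

check_scalar <- function(errors, deck, name, lo = -Inf, hi = Inf) {
  v <- tryCatch(get_param(deck, name), error = function(e) NULL)
  if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
    c(errors, paste0("missing or non-numeric: ", name))
  else if (v < lo || v > hi)
    c(errors, paste0(name, " = ", v, " outside [", lo, ", ", hi, "]"))
  else errors
}

#' Validate a parameter deck
#'
#' Checks schema completeness and every component invariant (probabilities
#' and utilities in \eqn{[0, 1]}, non-negative costs, positive survival
#' parameters, positive patient measurements). All violations are collected
#' and reported together, not just the first.
#'
#' @param deck A candidate deck.
#' @return \code{TRUE} invisibly, or an error listing every offending key.
#' @export
validate_deck <- function(deck) {
  e <- character(0)
  e <- check_scalar(e, deck, "settings.cycle_days", 1, 365)
  e <- check_scalar(e, deck, "settings.cost_cycle_days", 1, 365)
  e <- check_scalar(e, deck, "settings.horizon_years", 0.1, 100)
  e <- check_scalar(e, deck, "settings.discount_rate", 0, 1)
  e <- check_scalar(e, deck, "settings.wtp", 0)
  for (arm in arm_names()) {
    for (curve in c("os", "pfs")) {
      pre <- paste0("survival.", arm, ".", curve, ".")
      e <- check_scalar(e, deck, paste0(pre, "shape"), 1e-12)
      e <- check_scalar(e, deck, paste0(pre, "scale"), 1e-12)
    }
    for (ev in ae_events())
      e <- check_scalar(e, deck,
                        paste0("ae.incidence.", arm, ".", ev), 0, 1)
    e <- check_scalar(e, deck, paste0("subsequent.uptake.", arm), 0, 1)
  }
  for (p in c("tislelizumab", "etoposide", "cisplatin", "carboplatin"))
    e <- check_scalar(e, deck, paste0("prices.", p), 0)
  for (p in c("followup", "labs", "ct", "bsc"))
    e <- check_scalar(e, deck, paste0("care.", p), 0)
  for (p in ae_events())
    e <- check_scalar(e, deck, paste0("ae.costs.", p), 0)
  for (p in ae_events())
    e <- check_scalar(e, deck, paste0("ae.disutilities.", p), 0, 1)
  e <- check_scalar(e, deck, "utilities.pf", 0, 1)
  e <- check_scalar(e, deck, "utilities.pd", 0, 1)
  e <- check_scalar(e, deck, "subsequent.cost", 0)
  e <- check_scalar(e, deck, "patient.bsa_m2", 1e-6)
  e <- check_scalar(e, deck, "patient.gfr_ml_min", 0)
  e <- check_scalar(e, deck, "patient.body_weight_kg", 1e-6)
  e <- check_scalar(e, deck, "regimen.cisplatin_fraction", 0, 1)
  e <- check_scalar(e, deck, "regimen.induction_cycles", 0, 1000)
  if (length(e))
    stop("invalid parameter deck:\n  - ", paste(e, collapse = "\n  - "))
  invisible(TRUE)
}

## ---- file I/O --------------------------------------------------------------

#' Read / write a parameter deck (YAML)
#'
#' The deck is stored as a single human-editable YAML file; values round-trip
#' exactly (doubles are serialised with full precision). \code{read_deck}
#' validates the result before returning it.
#'
#' @param path File path.
#' @param deck A deck (for \code{write_deck}).
#' @return \code{read_deck}: a validated \code{cea_deck};
#'   \code{write_deck}: \code{path}, invisibly.
#' @examples
#' p <- file.path(tempdir(), "deck.yaml")
#' write_deck(base_deck(), p)
#' identical(unclass(read_deck(p)), unclass(base_deck()))
#' @export
read_deck <- function(path) {
  deck <- yaml::read_yaml(path)
  deck <- rapply(deck, function(x) {
    if (identical(x, ".inf")) Inf else x
  }, how = "replace")
  class(deck) <- c("cea_deck", "list")
  validate_deck(deck)
  deck
}

#' @rdname read_deck
#' @export
write_deck <- function(deck, path) {
  yaml::write_yaml(unclass(deck), path, precision = 15)
  invisible(path)
}

#' Deck checksum
#'
#' MD5 checksum of the deck's canonical YAML serialisation; changes if and
#' only if some deck value changes. Recorded in run manifests so a
#' reproduction attempt can confirm it used identical inputs.
#'
#' @param deck A parameter deck.
#' @return A 32-character hex string.
#' @export
deck_checksum <- function(deck) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_deck(deck, tf)
  unname(tools::md5sum(tf))
}
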