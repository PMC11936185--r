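# Shared fixtures for the test suite. Everything is generated in code.

table1_curves <- function() {
  list(
    tis_os = surv_dist("loglogistic", shape = 1.78, scale = 0.0068),
    chemo_os = surv_dist("loglogistic", shape = 2.37, scale = 0.0019),
    tis_pfs = surv_dist("loglogistic", shape = 1.92, scale = 0.035),
    chemo_pfs = surv_dist("loglogistic", shape = 3.97, scale = 0.0022)
  )
}

# One distribution per supported family, with medians around 5-15 months,
# used for family-wide property and recovery checks.
family_truths <- function() {
  list(
    exponential = surv_dist("exponential", scale = log(2) / 10),
    weibull = surv_dist("weibull", shape = 1.3, scale = log(2) / 10^1.3),
    gompertz = surv_dist("gompertz", shape = 0.1,
                         scale = log(2) * 0.1 / (exp(1) - 1)),
    gamma = surv_dist("gamma", shape = 2, scale = 0.17),
    lognormal = surv_dist("lognormal", shape = 0.8, scale = 10),
    loglogistic = surv_dist("loglogistic", shape = 1.92, scale = 0.035)
  )
}

# A random but valid deck: log-logistic survival parameters with medians in
# [2, 30] months and every varied cost/utility drawn uniformly within its
# sensitivity range.
random_deck <- function() {
  deck <- base_deck()
  rand_ll <- function() {
    g <- stats::runif(1, 0.6, 4)
    m <- stats::runif(1, 2, 30)
    list(family = "loglogistic", shape = g, scale = m^(-g))
  }
  for (arm in c("tislelizumab", "chemotherapy")) {
    deck$survival[[arm]]$os <- rand_ll()
    deck$survival[[arm]]$pfs <- rand_ll()
  }
  specs <- param_specs(deck)
  for (i in seq_len(nrow(specs)))
    deck <- set_param(deck, specs$name[i],
                      stats::runif(1, specs$low[i], specs$high[i]))
  deck
}

# Degenerate deck for hand-checkable accrual: one 21-day cycle, everyone
# progression-free, no adverse events, no discounting.
toy_deck <- function() {
  deck <- base_deck()
  deck$settings$horizon_years <- 21 / 365.25
  deck$settings$discount_rate <- 0
  for (arm in c("tislelizumab", "chemotherapy"))
    for (ev in names(deck$ae$incidence[[arm]]))
      deck$ae$incidence[[arm]][[ev]] <- 0
  deck
}

zero_cost_deck <- function() {
  deck <- base_deck()
  for (p in names(deck$prices)) deck$prices[[p]] <- 0
  for (p in names(deck$care)) deck$care[[p]] <- 0
  for (p in names(deck$ae$costs)) deck$ae$costs[[p]] <- 0
  deck$subsequent$cost <- 0
  deck
}
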