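test_that("digitized curves are normalised and repaired", {
  cur <- digitized_curve(c(3, 6), c(0.8, 0.6))
  expect_equal(cur$time[1L], 0)       # origin inserted
  expect_equal(cur$survival[1L], 1)
  cur2 <- digitized_curve(c(0, 3, 6), c(1, 0.6, 0.7))
  expect_true(attr(cur2, "repaired"))
  expect_equal(cur2$survival, c(1, 0.6, 0.6))  # running-minimum repair
  expect_error(digitized_curve(c(0, 0, 3), c(1, 1, 0.5)), "increasing")
  expect_error(digitized_curve(c(0, 3), c(1, 1.2)), "survival")
})

test_that("interval counts reconstruct events from survival drops", {
  cur <- digitized_curve(c(0, 6, 12), c(1, 0.5, 0.25), cohort_size = 100)
  ic <- interval_counts(cur)
  expect_equal(ic$events, c(50L, 25L))
  expect_equal(ic$at_risk, c(100L, 50L))
  expect_equal(attr(ic, "censored"), 25L)

  flat <- digitized_curve(c(0, 12), c(1, 1), cohort_size = 100)
  icf <- interval_counts(flat)
  expect_equal(icf$events, 0L)
  expect_equal(attr(icf, "censored"), 100L)

  expect_error(interval_counts(digitized_curve(0, 1)), "2 points")
})

test_that("fitting recovers generating parameters for every family", {
  # noiseless digitized curves on a half-month grid, cohort 5000
  grid <- seq(0, 36, by = 0.5)
  for (fam in names(family_truths())) {
    truth <- family_truths()[[fam]]
    cur <- digitized_curve(grid, psurv(truth, grid), label = fam,
                           cohort_size = 5000)
    fit <- fit_parametric(cur, fam)
    expect_true(fit$converged, info = fam)
    expect_equal(fit$distribution$scale, truth$scale, tolerance = 0.05,
                 info = fam)
    if (fam != "exponential")
      expect_equal(fit$distribution$shape, truth$shape, tolerance = 0.05,
                   info = fam)
  }
})

test_that("AIC/BIC identities hold and model selection prefers the truth", {
  grid <- seq(0, 36, by = 0.5)
  truth <- surv_dist("exponential", scale = log(2) / 10)
  cur <- digitized_curve(grid, psurv(truth, grid), cohort_size = 5000)
  fits <- fit_parametric(cur, "all")
  for (f in fits) {
    expect_equal(f$aic, 2 * f$n_params - 2 * f$log_likelihood)
    expect_equal(f$bic, f$n_params * log(5000) - 2 * f$log_likelihood)
  }
  # exponential truth: the 1-parameter family wins on AIC at large n
  expect_lte(fits$exponential$aic, fits$loglogistic$aic)
  best <- select_distribution(fits)
  expect_equal(best$family, "exponential")
  expect_s3_class(attr(best, "ranking"), "data.frame")
  expect_equal(nrow(attr(best, "ranking")), 6L)
})

test_that("selection uses min AIC with BIC and parsimony tie-breaks", {
  fit <- function(fam, ll, np) {
    structure(list(distribution = NULL, log_likelihood = ll,
                   aic = 2 * np - 2 * ll, bic = np * log(100) - 2 * ll,
                   n_params = np, n_effective = 100, converged = TRUE,
                   family = fam, label = "x"),
              class = "surv_fit")
  }
  f1 <- fit("weibull", -49.9, 2)   # aic 103.8
  f2 <- fit("gamma", -47.9, 2)     # aic 99.8
  f3 <- fit("lognormal", -49.7, 2) # aic 103.4
  expect_equal(select_distribution(list(f1, f2, f3))$family, "gamma")
  # AIC tie: the smaller BIC wins
  f4 <- fit("loglogistic", -48.9, 2)
  f5 <- fit("exponential", -49.9, 1)  # same aic 101.8, smaller bic
  expect_equal(select_distribution(list(f4, f5))$family, "exponential")
  expect_equal(select_distribution(list(f4))$family, "loglogistic")
  f_bad <- fit("gompertz", NA_real_, 2)
  f_bad$converged <- FALSE
  expect_error(select_distribution(list(f_bad)), "no converged")
})

test_that("degenerate curves are rejected, not mis-fit", {
  two <- digitized_curve(c(0, 6), c(1, 0.5))
  expect_error(fit_parametric(two, "loglogistic"), "3 points")
  flat <- digitized_curve(c(0, 6, 12), c(1, 1, 1))
  expect_error(fit_parametric(flat, "weibull"), "survival drop")
})

test_that("curve CSV round-trips through the two-column dialect", {
  cur <- digitized_curve(c(0, 3, 9), c(1, 0.7, 0.4), label = "demo",
                         cohort_size = 120)
  p <- withr::local_tempfile(fileext = ".csv")
  write_curve(cur, p)
  back <- read_curve(p, label = "demo", cohort_size = 120)
  expect_equal(back$time, cur$time)
  expect_equal(back$survival, cur$survival)
  rep_p <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_months,survival\n0,1\n3,0.5\n6,0.6", rep_p)
  expect_message(read_curve(rep_p), "repair")
})
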