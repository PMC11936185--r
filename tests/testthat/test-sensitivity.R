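test_that("one-way sensitivity: unused parameters yield zero swing", {
  deck <- base_deck()
  specs <- data.frame(
    name = c("patient.body_weight_kg",  # no dosing rule consumes weight
             "prices.tislelizumab"),
    base = c(60, 1.78), low = c(45, 1.34), high = c(75, 2.23),
    dist = "gamma", role = "cost"
  )
  torn <- one_way_sensitivity(deck, specs)
  weight <- torn[torn$parameter == "patient.body_weight_kg", ]
  expect_equal(weight$swing, 0)
  price <- torn[torn$parameter == "prices.tislelizumab", ]
  expect_gt(price$swing, 0)
  # degenerate range: swing 0
  degen <- data.frame(name = "care.bsc", base = 359.52, low = 359.52,
                      high = 359.52, dist = "gamma", role = "cost")
  expect_equal(one_way_sensitivity(deck, degen)$swing, 0)
  bad <- data.frame(name = "prices.nonexistent", base = 1, low = 0.5,
                    high = 2, dist = "gamma", role = "cost")
  expect_error(one_way_sensitivity(deck, bad), "unknown parameter")
})

test_that("tornado rows are sorted and the drug price ranks near the top", {
  torn <- one_way_sensitivity(base_deck())
  expect_true(all(diff(torn$swing) <= 0))
  expect_true("prices.tislelizumab" %in% torn$parameter[1:3])
  expect_true(any(grepl("^utilities\\.", torn$parameter[1:3])))
})

test_that("PSA draws are seed-reproducible and structurally sound", {
  deck <- base_deck()
  p1 <- run_psa(deck, iterations = 120, seed = 99)
  p2 <- run_psa(deck, iterations = 120, seed = 99)
  expect_identical(p1, p2)   # bit-identical on a shared seed
  p3 <- run_psa(deck, iterations = 120, seed = 100)
  expect_false(identical(p1$draws, p3$draws))
  expect_equal(nrow(p1$draws), 120L)
  expect_equal(p1$n_failed, 0L)
  expect_true(all(p1$draws$acceptable %in% c(TRUE, FALSE)))
  expect_gte(p1$acceptability, 0)
  expect_lte(p1$acceptability, 1)
})

test_that("degenerate fixed-parameter PSA collapses to the base case", {
  deck <- base_deck()
  specs <- param_specs(deck)
  specs$dist <- "fixed"
  psa <- run_psa(deck, iterations = 10, seed = 1, specs = specs)
  base <- run_cea(deck)
  expect_true(all(abs(psa$draws$d_cost - base$incremental$d_cost) < 1e-9))
  expect_true(all(abs(psa$draws$d_qaly - base$incremental$d_qaly) < 1e-9))
  # base-case point sits below the WTP ray, so acceptability is 1
  expect_equal(psa$acceptability, 1)
})

test_that("sampled parameters stay in support and centre on their base", {
  deck <- base_deck()
  psa <- run_psa(deck, iterations = 4000, seed = 5)
  specs <- param_specs(deck)
  for (i in seq_len(nrow(specs))) {
    m <- psa$param_means[[specs$name[i]]]
    sd_i <- (specs$high[i] - specs$low[i]) / 3.92
    # 4-sigma band on the Monte-Carlo mean
    expect_lt(abs(m - specs$base[i]), 4 * sd_i / sqrt(4000) + 1e-12)
  }
  # beta-drawn utilities stay in [0, 1]
  set.seed(2)
  for (rep in 1:200) {
    d <- sample_psa_deck(deck, specs)
    expect_true(d$utilities$pf >= 0 && d$utilities$pf <= 1)
    expect_true(d$regimen$cisplatin_fraction >= 0 &&
                  d$regimen$cisplatin_fraction <= 1)
    expect_true(d$prices$tislelizumab >= 0)
  }
})

test_that("CEAC agrees with the acceptability fraction and its limits", {
  psa <- run_psa(base_deck(), iterations = 300, seed = 12)
  cc <- ceac(psa, c(0, psa$wtp, 1e9))
  # at the deck WTP the curve equals the PSA acceptability exactly
  expect_identical(cc$probability[2L], psa$acceptability)
  # at lambda = 0: fraction of draws with non-positive incremental cost
  expect_identical(cc$probability[1L], mean(psa$draws$d_cost <= 0))
  # lambda large: fraction of draws with QALY gain (incl. boundary)
  expect_identical(cc$probability[3L],
                   mean(psa$draws$d_qaly >= psa$draws$d_cost / 1e9))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})
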