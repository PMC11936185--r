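test_that("cycle count and discount factors follow the settings", {
  deck <- base_deck()
  expect_identical(n_cycles(deck), 174L)
  expect_equal(discount_factor(0, deck), 1)
  expect_equal(discount_factor(18, deck), 0.95076, tolerance = 1e-5)
  flat <- set_param(deck, "settings.discount_rate", 0)
  expect_equal(discount_factor(c(0, 50, 173), flat), rep(1, 3))
  expect_error(discount_factor(-1, deck), "cycle_index")
})

test_that("the cohort trace satisfies its structural invariants", {
  deck <- base_deck()
  for (arm in c("tislelizumab", "chemotherapy")) {
    tr <- build_trace(deck, arm)
    expect_equal(nrow(tr), 174L)
    expect_equal(unlist(tr[1L, c("pf", "pd", "dead")]),
                 c(pf = 1, pd = 0, dead = 0))
    expect_equal(tr$discount[1L], 1)
    expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) <= 1e-12))
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$discount) < 0))
    expect_true(all(tr$new_pd >= 0))
  }
})

test_that("trace invariants hold across random parameter decks", {
  set.seed(7)
  for (rep in 1:20) {
    deck <- random_deck()
    tr <- build_trace(deck, sample(c("tislelizumab", "chemotherapy"), 1))
    expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) <= 1e-12))
    expect_true(all(tr$pf >= 0 & tr$pf <= 1 & tr$pd >= 0 & tr$pd <= 1))
    expect_true(all(diff(tr$dead) >= -1e-12))
  }
})

test_that("equal PFS and OS curves leave the progressed state empty", {
  deck <- base_deck()
  deck$survival$tislelizumab$pfs <- deck$survival$tislelizumab$os
  tr <- build_trace(deck, "tislelizumab")
  expect_true(all(tr$pd == 0))
})

test_that("a one-cycle progression-free trace accrues hand-computed costs", {
  deck <- toy_deck()
  res <- run_arm(deck, "tislelizumab")
  # induction drug + follow-up + labs + CT, undiscounted, one cycle
  expect_equal(res$cost, 622.815 + 55.60 + 92.50 + 105.90, tolerance = 1e-6)
  # QALYs: one cycle progression-free at utility 0.67
  expect_equal(res$qalys, 0.67 * 21 / 365.25, tolerance = 1e-9)
})

test_that("costs scale linearly and vanish on a zero-cost deck", {
  deck <- base_deck()
  zero <- zero_cost_deck()
  for (arm in c("tislelizumab", "chemotherapy"))
    expect_equal(run_arm(zero, arm)$cost, 0)
  doubled <- deck
  for (p in names(doubled$prices)) doubled$prices[[p]] <- 2 * doubled$prices[[p]]
  for (p in names(doubled$care)) doubled$care[[p]] <- 2 * doubled$care[[p]]
  for (p in names(doubled$ae$costs))
    doubled$ae$costs[[p]] <- 2 * doubled$ae$costs[[p]]
  doubled$subsequent$cost <- 2 * doubled$subsequent$cost
  for (arm in c("tislelizumab", "chemotherapy"))
    expect_equal(run_arm(doubled, arm)$cost, 2 * run_arm(deck, arm)$cost,
                 tolerance = 1e-12)
})

test_that("cost breakdown sums to the total and traces export to CSV", {
  deck <- base_deck()
  res <- run_arm(deck, "tislelizumab", keep_trace = TRUE)
  expect_equal(sum(res$breakdown), res$cost, tolerance = 1e-9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trace(res$trace, p)
  back <- read.csv(p)
  expect_equal(nrow(back), 174L)
  expect_equal(back$pf, res$trace$pf)
})

test_that("QALY accrual responds to utilities and discounting as it must", {
  deck <- base_deck()
  nod <- set_param(deck, "settings.discount_rate", 0)
  # utilities (1, 1), no discount, no adverse events: QALYs = life-years
  u1 <- nod
  u1$utilities <- list(pf = 1, pd = 1)
  for (ev in names(u1$ae$incidence$tislelizumab))
    u1$ae$incidence$tislelizumab[[ev]] <- 0
  res <- run_arm(u1, "tislelizumab")
  expect_equal(res$qalys, res$life_years, tolerance = 1e-9)
  # utilities (0, 0): QALYs are exactly minus the adverse-event loss
  u0 <- deck
  u0$utilities <- list(pf = 0, pd = 0)
  expect_equal(run_arm(u0, "tislelizumab")$qalys,
               -ae_burden(deck, "tislelizumab")$qaly_loss)
  # discounted total below undiscounted at a positive rate
  expect_lt(run_arm(deck, "tislelizumab")$qalys,
            run_arm(nod, "tislelizumab")$qalys)
  expect_lt(run_arm(deck, "tislelizumab")$cost,
            run_arm(nod, "tislelizumab")$cost)
  # monotone in each utility
  up <- set_param(deck, "utilities.pd", 0.6)
  expect_gt(run_arm(up, "tislelizumab")$qalys,
            run_arm(deck, "tislelizumab")$qalys)
})

test_that("halving the cycle length changes totals by less than 1%", {
  # under midpoint (half-cycle) accrual the scheme is second-order accurate,
  # so the cycle length is a pure discretization choice
  deck <- set_param(base_deck(), "settings.half_cycle", TRUE)
  half <- set_param(deck, "settings.cycle_days", 10.5)
  for (arm in c("tislelizumab", "chemotherapy")) {
    a <- run_arm(deck, arm)
    b <- run_arm(half, arm)
    expect_lt(abs(b$cost / a$cost - 1), 0.01)
    expect_lt(abs(b$qalys / a$qalys - 1), 0.01)
  }
  # default cycle-start accrual converges at first order: still stable,
  # with a discretization shift of order 1% when the step is halved
  d0 <- base_deck()
  h0 <- set_param(d0, "settings.cycle_days", 10.5)
  for (arm in c("tislelizumab", "chemotherapy")) {
    expect_lt(abs(run_arm(h0, arm)$cost / run_arm(d0, arm)$cost - 1), 0.025)
    expect_lt(abs(run_arm(h0, arm)$qalys / run_arm(d0, arm)$qalys - 1),
              0.025)
  }
})

test_that("run_arm is deterministic and the treatment cap bites", {
  deck <- base_deck()
  expect_identical(run_arm(deck, "tislelizumab"),
                   run_arm(deck, "tislelizumab"))
  capped <- set_param(deck, "settings.max_treatment_cycles", 8)
  expect_lt(run_arm(capped, "tislelizumab")$cost,
            run_arm(deck, "tislelizumab")$cost)
  # cap only affects drug acquisition
  expect_equal(run_arm(capped, "tislelizumab")$qalys,
               run_arm(deck, "tislelizumab")$qalys)
})

test_that("half-cycle correction evaluates occupancy at cycle midpoints", {
  deck <- base_deck()
  hc <- set_param(deck, "settings.half_cycle", TRUE)
  tr <- build_trace(hc, "tislelizumab")
  cm <- 21 / (365.25 / 12)
  expect_equal(tr$time_months[1L], cm / 2)
  expect_lt(tr$pf[1L], 1)
  expect_true(all(abs(tr$pf + tr$pd + tr$dead - 1) <= 1e-12))
  # midpoint evaluation lowers accrued QALYs slightly for a declining curve
  expect_lt(run_arm(hc, "tislelizumab")$qalys,
            run_arm(deck, "tislelizumab")$qalys)
})
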