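test_that("events prevented and absolute risk reduction follow the risk arithmetic", {
  ev <- events_prevented(2000, 0.12, 0.30)
  expect_equal(ev$events, 72)
  expect_equal(ev$arr_pct, 3.6)
  expect_equal(events_prevented(2000, 0.12, 0)$events, 0)
  expect_equal(events_prevented(2000, 0.20, 0.30)$events, 120)
  # linearity in each argument
  expect_equal(events_prevented(4000, 0.12, 0.30)$events_raw, 2 * ev$events_raw)
  expect_equal(events_prevented(2000, 0.24, 0.30)$events_raw, 2 * ev$events_raw)
  expect_equal(events_prevented(2000, 0.12, 0.15)$events_raw, ev$events_raw / 2)
})

test_that("per-case benefit lines multiply out to the published totals", {
  expect_equal(direct_savings(72, 421487), 30347064)
  expect_equal(round(direct_savings(72, 421487), -5), 30.3e6)
  expect_equal(direct_savings(0, 421487), 0)
  expect_equal(direct_savings(1, 421487), 421487)

  qa <- qaly_gains_and_value(72, 13.3, 100000)
  expect_equal(qa$qalys_raw, 957.6)
  expect_equal(qa$qalys, 958)
  expect_equal(qa$value, 95.8e6)
  expect_equal(qaly_gains_and_value(0, 13.3, 100000)$value, 0)
  qb <- qaly_gains_and_value(10, 12.4, 100000)
  expect_equal(qb$qalys, 124)
  expect_equal(qb$value, 12.4e6)

  expect_equal(productivity_savings(72, 200000), 14.4e6)
  expect_equal(productivity_savings(0, 200000), 0)
  expect_equal(productivity_savings(3, 200000), 6e5)

  expect_equal(cobenefit(30.3e6, 95.8e6, 14.4e6, 20e6, 0.15), 24.075e6)
  expect_equal(round(cobenefit(30.3e6, 95.8e6, 14.4e6, 20e6, 0.15), -5), 24.1e6)
  expect_equal(cobenefit(30.3e6, 95.8e6, 14.4e6, 20e6, 0), 0)
  expect_equal(cobenefit(100e6, 0, 0, 0, 0.15), 15e6)
})

test_that("the screening reconstruction reproduces both published totals jointly", {
  strat <- default_screening_strategies(default_parameters())
  uniform_cost <- screening_strategy_cost(strat$uniform)
  stratified_cost <- screening_strategy_cost(strat$stratified)
  # the single parameterization must match BOTH printed totals at once
  expect_equal(uniform_cost, 75e6)     # 10,000 x 30 years x $250
  expect_equal(stratified_cost, 55e6)  # 2,000 x 30 + 8,000 x 20, at $250
  expect_equal(screening_savings(strat$uniform, strat$stratified), 20e6)
  expect_equal(screening_savings(75e6, 55e6), 20e6)
  expect_error(screening_strategy(100, 50, 40), class = "prscea_domain_error")
})

test_that("program cost combines testing with the discounted medication stream", {
  p <- default_parameters()
  pc <- program_cost(p)
  expect_equal(pc$testing_total, 4e6)
  expect_equal(pc$statin_pv, 970000) # published convention
  expect_equal(pc$total, 4.97e6)

  # ordinary annuity convention, checked against a brute-force discounted sum
  pca <- program_cost(p, medication_pv = "annuity")
  flows <- sum(200 * 250 / 1.03^(1:30))
  expect_equal(pca$statin_pv, flows, tolerance = 1e-12)
  expect_equal(pca$statin_pv, 200 * 250 * annuity_factor(0.03, 30))
  # within ~1.1% of the published rounded figure
  expect_lt(abs(pca$statin_pv - 970000) / 970000, 0.011)

  # undiscounted limit
  p0 <- set_fixed(p, "discount_rate", 0)
  expect_equal(program_cost(p0, "annuity")$statin_pv, 200 * 250 * 30) # $1.5M
})

test_that("the base-case ledger reproduces the published accounting line by line", {
  led <- benefit_ledger(default_parameters())
  v <- glance(led)
  expect_equal(v$events, 72)
  expect_equal(v$arr_pct, 3.6)
  expect_equal(v$direct_savings, 30.3e6)
  expect_equal(v$qalys, 958)
  expect_equal(v$qaly_value, 95.8e6)
  expect_equal(v$productivity, 14.4e6)
  expect_equal(v$screening_savings, 20e6)
  expect_equal(v$cobenefit, 24.1e6)
  expect_equal(v$total_benefit, 184.6e6)
  # additivity of the five reported lines
  expect_equal(v$total_benefit,
               v$direct_savings + v$qaly_value + v$productivity +
                 v$screening_savings + v$cobenefit)
  expect_equal(v$program_cost, 4.97e6)
  expect_equal(round(v$roi_pct), 3614)
  expect_equal(round(v$icer), 5188)
  expect_equal(v$breakeven_cases, 2)
  expect_equal(v$breakeven_cases_direct, 3)
  expect_equal(v$npv_adjusted / 1e6, 328.8, tolerance = 1e-3)
  expect_equal(v$roi_adjusted_pct, 6515, tolerance = 1e-3)

  lines <- tidy(led)
  expect_identical(lines$item[nrow(lines)], "total_benefit")
  expect_equal(lines$reported[lines$item == "qalys"], 958)
})

test_that("adjusted NPV and ROI respect the rate-cancellation identities", {
  adj <- adjusted_npv_roi(184.6e6, 4.97e6, 0.05, 0.03, 30)
  expect_equal(adj$npv / 1e6, 328.8, tolerance = 1e-3)
  expect_equal(adj$roi_adjusted_pct, 6515, tolerance = 1e-3)
  # inflation equal to discount leaves the benefit untouched
  same <- adjusted_npv_roi(184.6e6, 4.97e6, 0.03, 0.03, 30)
  expect_equal(same$npv, 184.6e6)
  expect_equal(same$roi_adjusted_pct, 100 * (184.6e6 - 4.97e6) / 4.97e6)
  # zero horizon is the identity
  expect_equal(adjusted_npv_roi(184.6e6, 4.97e6, 0.05, 0.03, 0)$npv, 184.6e6)
  expect_error(adjusted_npv_roi(1e6, 1e5, 0.5, 0.03, 30))
})

test_that("zero intervention effect drives the ledger to total loss", {
  p <- set_fixed(default_parameters(), "relative_risk_reduction", 0)
  # align the two screening schedules so no benefit line survives
  p <- set_fixed(p, "screening_start_low", 40)
  v <- glance(benefit_ledger(p))
  expect_equal(v$events, 0)
  expect_equal(v$total_benefit, 0)
  expect_equal(v$roi_pct, -100)
})

test_that("ROI falls with cost and ICER falls with QALYs", {
  v <- glance(benefit_ledger(default_parameters()))
  costs <- c(2e6, 4.97e6, 10e6, 20e6)
  rois <- 100 * (v$total_benefit - costs) / costs
  expect_true(all(diff(rois) < 0))
  qalys <- c(500, 958, 1500)
  icers <- v$program_cost / qalys
  expect_true(all(diff(icers) < 0))
})

test_that("ledger exports round-trip through JSON and CSV", {
  led <- benefit_ledger(default_parameters())
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_ledger_json(led, jpath)
  write_ledger_csv(led, cpath)
  j <- jsonlite::read_json(jpath)
  expect_equal(j$total_benefit, 184.6e6)
  expect_equal(j$events_raw, 72)
  got <- utils::read.csv(cpath)
  expect_equal(got$roi_pct, glance(led)$roi_pct)
})
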