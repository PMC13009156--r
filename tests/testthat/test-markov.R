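test_that("risk annualization matches its closed form and inverts by compounding", {
  expect_equal(annualize_risk(0.12, 10), 1 - 0.88^0.1)
  expect_equal(annualize_risk(0.12, 10), 0.0127019, tolerance = 1e-5)
  expect_identical(annualize_risk(0, 10), 0)
  expect_equal(annualize_risk(0.37, 1), 0.37)
  # compounding the annual probability over k years recovers the cumulative risk
  for (p in c(0.01, 0.12, 0.5, 0.9)) {
    for (k in c(1, 5, 10, 30)) {
      a <- annualize_risk(p, k)
      expect_equal(1 - (1 - a)^k, p, tolerance = 1e-12)
    }
  }
  expect_error(annualize_risk(1, 10), class = "prscea_domain_error")
})

test_that("transition tables carry the annualized hazards with the stated structure", {
  params <- set_fixed(default_parameters(), "stroke_incidence_10y_top20", 0)
  h <- annualize_risk(0.12, 10)

  std <- build_transition_table(params, "next18", "standard")
  at45 <- std[std$age == 45, ]
  expect_equal(at45$p_nonfatal_event + at45$p_fatal_event, h)
  expect_equal(at45$p_fatal_event, 0.20 * h) # acute fatality split
  expect_false(attr(std, "intervention_active"))

  guided <- build_transition_table(params, "next18", "prs_guided")
  at45g <- guided[guided$age == 45, ]
  expect_equal(at45g$p_nonfatal_event + at45g$p_fatal_event, h * 0.70)
  expect_true(attr(guided, "intervention_active"))
  expect_false(attr(guided, "statin_active"))
  expect_true(attr(build_transition_table(params, "top2", "prs_guided"),
                   "statin_active"))

  # no events before age 40, in any stratum
  for (stratum in c("top2", "next18", "bottom80")) {
    tab <- build_transition_table(default_parameters(), stratum, "standard")
    young <- tab[tab$age < 40, ]
    expect_true(all(young$p_nonfatal_event == 0 & young$p_fatal_event == 0))
  }
  # the bottom 80% carries no event hazard by default
  low <- build_transition_table(default_parameters(), "bottom80", "prs_guided")
  expect_true(all(low$p_nonfatal_event == 0 & low$p_fatal_event == 0))
})

test_that("cohort traces conserve mass, keep deaths absorbing, and hit limits", {
  zero <- set_fixed(set_fixed(default_parameters(),
                              "cad_incidence_10y_top20", 0),
                    "stroke_incidence_10y_top20", 0)
  tr0 <- run_cohort_trace(build_transition_table(zero, "next18", "standard"))
  expect_true(all(tr0$event_free == 1))

  # immediate non-CV death absorbs the whole cohort after one cycle
  dead <- build_transition_table(default_parameters(), "bottom80", "standard",
                                 background_mortality = 1, event_start_age = 10)
  trd <- run_cohort_trace(dead)
  expect_true(all(trd$noncv_death[trd$cycle >= 1] == 1))

  for (seed in 1:4) {
    p <- perturbed_parameters(seed, jitter = 0.1)
    for (arm in c("standard", "prs_guided")) {
      tr <- run_cohort_trace(build_transition_table(p, "top2", arm))
      occ <- tr$event_free + tr$post_event + tr$cv_death + tr$noncv_death
      expect_true(all(abs(occ - 1) < 1e-9))
      expect_true(all(diff(tr$cv_death) >= 0))
      expect_true(all(diff(tr$noncv_death) >= 0))
      # survival (1 - total deaths) never increases
      expect_true(all(diff(1 - tr$cv_death - tr$noncv_death) <= 1e-12))
    }
  }
})

test_that("a three-cycle trace matches explicit matrix multiplication", {
  tab <- tibble::tibble(
    age = 10:12,
    p_nonfatal_event = c(0.10, 0.20, 0.05),
    p_fatal_event = c(0.05, 0.10, 0.20),
    p_noncv_death = c(0.02, 0.05, 0.10)
  )
  tab$p_stay <- 1 - tab$p_nonfatal_event - tab$p_fatal_event - tab$p_noncv_death
  trace <- run_cohort_trace(tab)

  # independent oracle: state row-vector times the annual transition matrix
  v <- c(1, 0, 0, 0)
  for (t in 1:3) {
    M <- rbind(
      c(tab$p_stay[t], tab$p_nonfatal_event[t], tab$p_fatal_event[t], tab$p_noncv_death[t]),
      c(0, 1 - tab$p_noncv_death[t], 0, tab$p_noncv_death[t]),
      c(0, 0, 1, 0),
      c(0, 0, 0, 1)
    )
    v <- as.numeric(v %*% M)
    got <- unlist(trace[trace$cycle == t,
                        c("event_free", "post_event", "cv_death", "noncv_death")])
    expect_equal(unname(got), v, tolerance = 1e-15)
  }
})

test_that("cumulative event incidence over the first risk decade recovers 12%", {
  # stroke and competing mortality switched off: only the CAD hazard acts
  params <- set_fixed(default_parameters(), "stroke_incidence_10y_top20", 0)
  tr <- run_cohort_trace(build_transition_table(params, "next18", "standard"))
  cum_inc <- 1 - tr$event_free[tr$age == 50]
  expect_equal(cum_inc, 0.12, tolerance = 1e-9)
})

test_that("trace summaries credit age-banded, discounted utilities correctly", {
  base <- set_fixed(set_fixed(default_parameters(),
                              "cad_incidence_10y_top20", 0),
                    "stroke_incidence_10y_top20", 0)
  flat <- base
  for (u in c("utility_10_40", "utility_40_60", "utility_60plus"))
    flat <- set_fixed(flat, u, 1)
  flat0 <- set_fixed(flat, "discount_rate", 0)
  tr <- run_cohort_trace(build_transition_table(flat0, "next18", "standard"))
  s <- summarize_trace(tr, flat0)
  expect_equal(s$life_expectancy, 80) # all 70 years lived from age 10
  expect_equal(s$discounted_qalys, 70)

  banded0 <- set_fixed(base, "discount_rate", 0)
  sb <- summarize_trace(tr, banded0)
  expect_equal(sb$discounted_qalys, 30 * 0.95 + 20 * 0.92 + 20 * 0.85) # 63.9

  # discounting strictly reduces QALYs, and more so at higher rates
  s3 <- summarize_trace(tr, base) # 3% discount
  expect_lt(s3$discounted_qalys, sb$discounted_qalys)
  s5 <- summarize_trace(tr, set_fixed(base, "discount_rate", 0.05))
  expect_lt(s5$discounted_qalys, s3$discounted_qalys)
  expect_lte(s3$discounted_qalys, s3$discounted_life_years)
})

test_that("scenario deltas reproduce the printed gradient differences", {
  sc <- scenario_fixtures()
  no_prev <- sc[sc$name == "high_prs_no_prevention", ]
  with_prev <- sc[sc$name == "high_prs_with_prevention", ]
  low <- sc[sc$name == "low_prs", ]

  d <- project_scenario_delta(no_prev, with_prev)
  expect_equal(d$delta[d$metric == "life_expectancy"], 7)
  expect_equal(d$delta[d$metric == "qalys"], 13.3)

  grad <- project_scenario_delta(low, no_prev)
  expect_equal(grad$fold_change[grad$metric == "fatal_mi"], 5) # fivefold

  same <- project_scenario_delta(low, low)
  expect_true(all(same$delta == 0))
})

test_that("trace CSV export carries occupancies and cumulative discounted rewards", {
  p <- default_parameters()
  tr <- run_cohort_trace(build_transition_table(p, "top2", "prs_guided"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, p, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), nrow(tr))
  expect_equal(got$event_free, tr$event_free)
  expect_true(all(diff(got$cum_discounted_qaly) >= 0))
  expect_equal(got$cum_discounted_ly[nrow(got)],
               summarize_trace(tr, p)$discounted_life_years)
})
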