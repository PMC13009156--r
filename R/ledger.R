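# Societal cost-benefit ledger ------------------------------------------------
#
# Deterministic accounting of program costs and benefits over the modeled
# cohort: events prevented, direct healthcare savings, monetized QALYs,
# productivity, screening-stratification savings, indirect co-benefits,
# ROI, ICER, break-even, and the inflation/discount-adjusted NPV and ROI.
#
# Reporting convention: monetary line items are rounded to $0.1M and QALYs
# to an integer BEFORE summation, so the reported total matches the sum of
# its reported lines; unrounded values are retained alongside.

round_m <- function(usd) round(usd, -5) # nearest $0.1 million

#' Cardiovascular events prevented by risk-stratified prevention
#'
#' `events = n_high * incidence_10y * rrr`, with the absolute risk reduction
#' `arr = 100 * incidence_10y * rrr` (% of the high-risk group).
#'
#' @param n_high Number of high-risk individuals under intervention.
#' @param incidence_10y 10-year event incidence in the high-risk group.
#' @param rrr Relative risk reduction of the intervention.
#' @return One-row tibble: `events_raw`, `events` (rounded to integer),
#'   `arr_pct`.
#' @examples
#' events_prevented(2000, 0.12, 0.30) # 72 events, ARR 3.6%
#' @export
events_prevented <- function(n_high, incidence_10y, rrr) {
  stopifnot(n_high >= 0, incidence_10y >= 0, incidence_10y <= 1)
  raw <- n_high * incidence_10y * rrr
  tibble::tibble(events_raw = raw, events = round(raw),
                 arr_pct = 100 * incidence_10y * rrr)
}

#' Direct healthcare savings from prevented events
#'
#' @param events Events prevented.
#' @param lifetime_cost Lifetime direct cost per case (USD).
#' @return Savings in USD.
#' @export
direct_savings <- function(events, lifetime_cost) {
  stopifnot(events >= 0, lifetime_cost >= 0)
  events * lifetime_cost
}

#' QALYs gained and their monetary value
#'
#' QALYs are reported rounded to an integer; their monetary value uses the
#' reported QALY count.
#'
#' @param events Events prevented.
#' @param per_case_qalys QALYs gained per prevented case.
#' @param qaly_price Monetary value per QALY (USD).
#' @return One-row tibble: `qalys_raw`, `qalys`, `value_raw`, `value`.
#' @examples
#' qaly_gains_and_value(72, 13.3, 100000) # 958 QALYs, $95.8M
#' @export
qaly_gains_and_value <- function(events, per_case_qalys, qaly_price) {
  stopifnot(events >= 0, per_case_qalys >= 0, qaly_price >= 0)
  raw <- events * per_case_qalys
  rep <- round(raw)
  tibble::tibble(qalys_raw = raw, qalys = rep,
                 value_raw = raw * qaly_price, value = rep * qaly_price)
}

#' Productivity savings from prevented events
#'
#' @param events Events prevented.
#' @param per_case Productivity savings per case (USD).
#' @return Savings in USD.
#' @export
productivity_savings <- function(events, per_case) {
  stopifnot(events >= 0, per_case >= 0)
  events * per_case
}

#' Define a screening strategy
#'
#' A strategy is a set of groups screened at a given annual frequency and
#' unit cost over an age window; costs are undiscounted.
#'
#' @param n_people,start_age,end_age,screens_per_year,unit_cost Vectors
#'   (recycled) describing each group.
#' @return A tibble with one row per group and a `years` column.
#' @export
screening_strategy <- function(n_people, start_age, end_age,
                               screens_per_year = 1, unit_cost = 250) {
  out <- tibble::tibble(n_people = n_people, start_age = start_age,
                        end_age = end_age,
                        screens_per_year = screens_per_year,
                        unit_cost = unit_cost)
  if (any(out$end_age < out$start_age))
    abort("`end_age` must be >= `start_age`.", class = "prscea_domain_error")
  out$years <- out$end_age - out$start_age
  out
}

#' Total undiscounted cost of a screening strategy
#'
#' @param strategy A tibble from [screening_strategy()].
#' @return Total cost in USD.
#' @export
screening_strategy_cost <- function(strategy) {
  sum(strategy$n_people * strategy$years * strategy$screens_per_year *
        strategy$unit_cost)
}

#' Savings of a stratified screening strategy over a uniform one
#'
#' @param uniform,stratified Strategies ([screening_strategy()] tibbles) or
#'   precomputed total costs (USD).
#' @return Savings in USD (uniform minus stratified).
#' @export
screening_savings <- function(uniform, stratified) {
  cost <- function(x) if (is.data.frame(x)) screening_strategy_cost(x) else x
  cost(uniform) - cost(stratified)
}

#' Default screening strategies implied by the parameter set
#'
#' Uniform: the whole cohort screened annually from age 40 to the screening
#' end age. Stratified: the high-risk 20% screened annually from age 40 and
#' the remainder from age 50.
#'
#' @param params A `parameter_set`.
#' @return A list with elements `uniform` and `stratified`.
#' @export
default_screening_strategies <- function(params) {
  n <- param_value(params, "cohort_size")
  n_high <- n * param_value(params, "high_risk_fraction")
  cost <- param_value(params, "screening_unit_cost", default = 250)
  end <- param_value(params, "screening_end_age", default = 70)
  s_high <- param_value(params, "screening_start_high", default = 40)
  s_low <- param_value(params, "screening_start_low", default = 50)
  list(
    uniform = screening_strategy(n, s_high, end, 1, cost),
    stratified = screening_strategy(c(n_high, n - n_high), c(s_high, s_low),
                                    end, 1, cost)
  )
}

#' Indirect health co-benefits
#'
#' A single multiplier applied to the sum of the four direct benefit lines,
#' standing in for reductions in comorbid conditions (type 2 diabetes,
#' certain cancers, depression) from the same lifestyle interventions.
#'
#' @param direct,qaly_value,productivity,screening Benefit lines (USD).
#' @param multiplier Co-benefit multiplier (fraction).
#' @return Co-benefit in USD.
#' @export
cobenefit <- function(direct, qaly_value, productivity, screening, multiplier) {
  stopifnot(multiplier >= 0)
  multiplier * (direct + qaly_value + productivity + screening)
}

#' Present value of an ordinary annuity
#'
#' `(1 - (1 + rate)^-years) / rate` (end-of-year payments; `years` at rate 0).
#'
#' @param rate Annual discount rate.
#' @param years Number of annual payments.
#' @return Annuity factor.
#' @export
annuity_factor <- function(rate, years) {
  stopifnot(rate >= 0, years >= 0)
  if (rate == 0) years else (1 - (1 + rate)^-years) / rate
}

#' Program implementation cost
#'
#' One-time genetic testing for the whole cohort plus the discounted present
#' value of statin therapy and monitoring for the very-high-risk subgroup
#' over the program horizon. Two medication-PV conventions are available:
#' `"printed"` (default) uses the published discounted PV through its
#' implied annuity factor (parameter `statin_annuity_printed`, 19.4 per $1
#' of annual cost), so the base case reproduces the published $970,000 and
#' $4.97M total; `"annuity"` computes the ordinary annuity at the discount
#' rate over the horizon ($980,022 at 3% over 30 years, within 1.1% of the
#' published figure).
#'
#' @param params A `parameter_set`.
#' @param medication_pv `"printed"` or `"annuity"`.
#' @return One-row tibble: `testing_total`, `statin_pv`, `statin_pv_annuity`,
#'   `total`, `medication_pv`.
#' @export
program_cost <- function(params, medication_pv = c("printed", "annuity")) {
  medication_pv <- match.arg(medication_pv)
  n <- param_value(params, "cohort_size")
  treated <- n * param_value(params, "very_high_risk_fraction")
  testing <- n * param_value(params, "genetic_test_cost")
  annual <- param_value(params, "statin_monitoring_annual_cost")
  af <- annuity_factor(param_value(params, "discount_rate"),
                       param_value(params, "horizon_years"))
  pv_annuity <- treated * annual * af
  af_printed <- param_value(params, "statin_annuity_printed", default = NA_real_)
  pv <- if (medication_pv == "printed" && is.finite(af_printed))
    treated * annual * af_printed else pv_annuity
  tibble::tibble(testing_total = testing, statin_pv = pv,
                 statin_pv_annuity = pv_annuity, total = testing + pv,
                 medication_pv = medication_pv)
}

#' Inflation- and discount-adjusted net present value and ROI
#'
#' Benefits are compounded jointly by medical inflation and discounting:
#' `NPV = total_benefit * ((1 + inflation) / (1 + discount))^years`;
#' adjusted ROI is `100 * (NPV - cost) / cost`.
#'
#' @param total_benefit Total societal benefit (USD, today's dollars).
#' @param cost Program cost (USD).
#' @param inflation Annual medical inflation rate.
#' @param discount Annual discount rate.
#' @param years Adjustment horizon (years).
#' @return One-row tibble: `npv`, `roi_adjusted_pct`.
#' @export
adjusted_npv_roi <- function(total_benefit, cost, inflation, discount, years) {
  stopifnot(inflation >= 0, inflation <= 0.2, discount >= 0, discount <= 0.2)
  npv <- total_benefit * ((1 + inflation) / (1 + discount))^years
  tibble::tibble(npv = npv, roi_adjusted_pct = 100 * (npv - cost) / cost)
}

# Full ledger as a named numeric vector (fast path shared with the PSA).
ledger_values <- function(params, medication_pv = "printed") {
  n_high <- param_value(params, "cohort_size") *
    param_value(params, "high_risk_fraction")
  ev <- events_prevented(n_high,
                         param_value(params, "cad_incidence_10y_top20"),
                         param_value(params, "relative_risk_reduction"))
  dir_raw <- direct_savings(ev$events_raw, param_value(params, "lifetime_cad_cost"))
  qa <- qaly_gains_and_value(ev$events_raw,
                             param_value(params, "qaly_gain_per_case"),
                             param_value(params, "qaly_monetary_value"))
  prod_raw <- productivity_savings(ev$events_raw,
                                   param_value(params, "productivity_per_case"))
  strat <- default_screening_strategies(params)
  screen <- screening_savings(strat$uniform, strat$stratified)
  mult <- param_value(params, "cobenefit_multiplier")

  dir_rep <- round_m(dir_raw)
  qv_rep <- round_m(qa$value)
  prod_rep <- round_m(prod_raw)
  screen_rep <- round_m(screen)
  cob_raw <- cobenefit(dir_raw, qa$value_raw, prod_raw, screen, mult)
  cob_rep <- round_m(cobenefit(dir_rep, qv_rep, prod_rep, screen_rep, mult))
  total_raw <- dir_raw + qa$value_raw + prod_raw + screen + cob_raw
  total_rep <- dir_rep + qv_rep + prod_rep + screen_rep + cob_rep

  pc <- program_cost(params, medication_pv)
  cost <- pc$total
  roi <- 100 * (total_rep - cost) / cost
  roi_raw <- 100 * (total_raw - cost) / cost
  icer <- cost / qa$qalys
  icer_raw <- cost / qa$qalys_raw
  per_case_total <- total_rep / ev$events
  per_case_direct <- param_value(params, "lifetime_cad_cost") +
    param_value(params, "qaly_gain_per_case") *
      param_value(params, "qaly_monetary_value") +
    param_value(params, "productivity_per_case")
  adj <- adjusted_npv_roi(total_rep, cost,
                          param_value(params, "medical_inflation"),
                          param_value(params, "discount_rate"),
                          param_value(params, "horizon_years"))

  c(events_raw = ev$events_raw, events = ev$events, arr_pct = ev$arr_pct,
    direct_savings_raw = dir_raw, direct_savings = dir_rep,
    qalys_raw = qa$qalys_raw, qalys = qa$qalys,
    qaly_value_raw = qa$value_raw, qaly_value = qv_rep,
    productivity_raw = prod_raw, productivity = prod_rep,
    screening_savings_raw = screen, screening_savings = screen_rep,
    cobenefit_raw = cob_raw, cobenefit = cob_rep,
    total_benefit_raw = total_raw, total_benefit = total_rep,
    testing_cost = pc$testing_total, statin_pv = pc$statin_pv,
    program_cost = cost,
    roi_pct = roi, roi_pct_raw = roi_raw,
    icer = icer, icer_raw = icer_raw,
    breakeven_cases = ceiling(cost / per_case_total),
    breakeven_cases_direct = ceiling(cost / per_case_direct),
    npv_adjusted = adj$npv, roi_adjusted_pct = adj$roi_adjusted_pct)
}

#' Compute the full societal cost-benefit ledger
#'
#' Runs every accounting step on a parameter set: events prevented in the
#' high-risk group, direct healthcare savings, QALYs gained and their
#' monetary value, productivity savings, screening-stratification savings,
#' the indirect co-benefit line, total societal benefit, ROI, ICER (gross
#' program cost per QALY gained), break-even case counts (per-case benefit
#' from the full ledger, and from the direct per-case bundle), and the
#' inflation/discount-adjusted NPV and ROI. Reported monetary lines are
#' rounded to $0.1M (QALYs to an integer) before summation; `_raw` fields
#' keep the unrounded values.
#'
#' @param params A `parameter_set`.
#' @param medication_pv Medication present-value convention, see
#'   [program_cost()].
#' @return A `benefit_ledger` object; use [tidy()] for the line items and
#'   [glance()] for the one-row summary.
#' @examples
#' led <- benefit_ledger(default_parameters())
#' glance(led)
#' @export
benefit_ledger <- function(params, medication_pv = c("printed", "annuity")) {
  medication_pv <- match.arg(medication_pv)
  validate_parameter_set(params)
  v <- ledger_values(params, medication_pv)
  structure(
    list(values = v, medication_pv = medication_pv,
         program_cost = program_cost(params, medication_pv)),
    class = "benefit_ledger")
}

#' @export
print.benefit_ledger <- function(x, ...) {
  v <- x$values
  cat("PRS-guided CAD prevention: societal cost-benefit ledger\n")
  cat(sprintf("  Events prevented       %8.0f  (ARR %.1f%%)\n",
              v[["events"]], v[["arr_pct"]]))
  cat(sprintf("  Direct savings         $%6.1fM\n", v[["direct_savings"]] / 1e6))
  cat(sprintf("  QALYs gained           %8.0f  ($%.1fM)\n",
              v[["qalys"]], v[["qaly_value"]] / 1e6))
  cat(sprintf("  Productivity           $%6.1fM\n", v[["productivity"]] / 1e6))
  cat(sprintf("  Screening savings      $%6.1fM\n", v[["screening_savings"]] / 1e6))
  cat(sprintf("  Co-benefits            $%6.1fM\n", v[["cobenefit"]] / 1e6))
  cat(sprintf("  Total societal benefit $%6.1fM\n", v[["total_benefit"]] / 1e6))
  cat(sprintf("  Program cost           $%6.2fM\n", v[["program_cost"]] / 1e6))
  cat(sprintf("  ROI %.0f%%   ICER $%.0f/QALY   break-even %d-%d cases\n",
              v[["roi_pct"]], v[["icer"]], v[["breakeven_cases"]],
              v[["breakeven_cases_direct"]]))
  cat(sprintf("  Adjusted NPV $%.1fM   adjusted ROI %.0f%%\n",
              v[["npv_adjusted"]] / 1e6, v[["roi_adjusted_pct"]]))
  invisible(x)
}

#' Tidy the ledger line items
#'
#' @param x A `benefit_ledger`.
#' @param ... Unused.
#' @return A tibble with one row per line item: `item`, `raw`, `reported`.
#' @method tidy benefit_ledger
#' @export
tidy.benefit_ledger <- function(x, ...) {
  v <- x$values
  items <- c("events", "arr_pct", "direct_savings", "qalys", "qaly_value",
             "productivity", "screening_savings", "cobenefit", "total_benefit")
  raw_names <- paste0(items, "_raw")
  raw <- ifelse(raw_names %in% names(v), v[raw_names], v[items])
  tibble::tibble(item = items, raw = unname(raw), reported = unname(v[items]))
}

#' One-row summary of a ledger
#'
#' @param x A `benefit_ledger`.
#' @param ... Unused.
#' @return A one-row tibble with every ledger field.
#' @method glance benefit_ledger
#' @export
glance.benefit_ledger <- function(x, ...) {
  tibble::as_tibble(as.list(x$values))
}

#' Export a ledger as JSON (all fields, rounded and unrounded) or CSV
#'
#' @param ledger A `benefit_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(as.list(ledger$values), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_ledger_json
#' @export
write_ledger_csv <- function(ledger, path) {
  write.csv(as.data.frame(glance(ledger)), path, row.names = FALSE)
  invisible(path)
}
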