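# Four-state Markov cohort engine --------------------------------------------
#
# States: EVENT_FREE, POST_EVENT (post nonfatal MI/stroke), CV_DEATH,
# NONCV_DEATH. Annual cycles from entry at age 10 to age 80; transitions at
# cycle end, rewards credited to the state occupied during the cycle (no
# half-cycle correction). Death states are absorbing; no recurrent events.

health_states <- c("event_free", "post_event", "cv_death", "noncv_death")

#' Convert a cumulative multi-year risk to a constant annual probability
#'
#' `1 - (1 - p_cum)^(1/years)`; compounding the result over `years` cycles
#' recovers `p_cum`.
#'
#' @param p_cum Cumulative risk over the period, in \[0, 1).
#' @param years Number of years in the period (positive integer).
#' @return Annual probability.
#' @examples
#' annualize_risk(0.12, 10)
#' @export
annualize_risk <- function(p_cum, years) {
  if (!is.numeric(p_cum) || any(p_cum < 0) || any(p_cum >= 1))
    abort("`p_cum` must lie in [0, 1); a certain event cannot be annualized.",
          class = "prscea_domain_error")
  if (!is.numeric(years) || any(years < 1))
    abort("`years` must be a positive integer.", class = "prscea_domain_error")
  1 - (1 - p_cum)^(1 / years)
}

#' Build the annual transition table for one PRS stratum and arm
#'
#' One row per age from entry to end of follow-up, with annual probabilities
#' of a nonfatal cardiovascular event, a fatal event, and non-cardiovascular
#' death, for a given PRS stratum (`top2`, `next18`, `bottom80`) and arm
#' (`standard`, `prs_guided`). Event hazards are zero before
#' `event_start_age` (default 40). From age 40 the high-PRS strata carry the
#' annualized 10-year CAD and stroke incidences; under the PRS-guided arm
#' the top 20% strata have event hazards multiplied by
#' `1 - relative_risk_reduction`. The fatal share of events is the acute
#' case-fatality parameter. The bottom 80% stratum carries no printed
#' incidence and defaults to zero event hazard. Non-CV mortality defaults to
#' zero (none is modeled before age 40); a background annual probability
#' (scalar or per-age vector for ages >= 40) can be supplied.
#'
#' @param params A `parameter_set`.
#' @param stratum One of `"top2"`, `"next18"`, `"bottom80"`.
#' @param arm One of `"standard"`, `"prs_guided"`.
#' @param background_mortality Annual non-CV death probability applied from
#'   `event_start_age` (scalar or vector over those ages). Default 0.
#' @param entry_age,end_age Follow-up window (defaults 10 and 80).
#' @param event_start_age Age at which cardiovascular events begin (default 40).
#' @return A `transition_table` tibble with columns `age`, `p_nonfatal_event`,
#'   `p_fatal_event`, `p_noncv_death`, `p_stay`, carrying the stratum/arm
#'   flags as attributes.
#' @export
build_transition_table <- function(params, stratum, arm,
                                   background_mortality = 0,
                                   entry_age = 10, end_age = 80,
                                   event_start_age = 40) {
  stratum <- match.arg(stratum, c("top2", "next18", "bottom80"))
  arm <- match.arg(arm, c("standard", "prs_guided"))
  intervention_active <- arm == "prs_guided" && stratum %in% c("top2", "next18")
  statin_active <- intervention_active && stratum == "top2"

  ages <- seq.int(entry_age, end_age - 1L)
  high_prs <- stratum %in% c("top2", "next18")
  p_cad10 <- if (high_prs) param_value(params, "cad_incidence_10y_top20") else 0
  p_str10 <- if (high_prs) param_value(params, "stroke_incidence_10y_top20") else 0
  h_cad <- annualize_risk(p_cad10, 10)
  h_str <- annualize_risk(p_str10, 10)
  if (intervention_active) {
    rrr <- param_value(params, "relative_risk_reduction")
    h_cad <- h_cad * (1 - rrr)
    h_str <- h_str * (1 - rrr)
  }
  # independent CAD and stroke hazards combined into one event probability
  p_event <- ifelse(ages >= event_start_age, 1 - (1 - h_cad) * (1 - h_str), 0)
  fatality <- param_value(params, "cad_fatality")

  post40 <- ages >= event_start_age
  p_noncv <- numeric(length(ages))
  if (length(background_mortality) == 1L) {
    p_noncv[post40] <- background_mortality
  } else {
    if (length(background_mortality) != sum(post40))
      abort("`background_mortality` must be scalar or one value per age >= event_start_age.",
            class = "prscea_domain_error")
    p_noncv[post40] <- background_mortality
  }

  tab <- tibble::tibble(
    age = ages,
    p_nonfatal_event = (1 - fatality) * p_event,
    p_fatal_event = fatality * p_event,
    p_noncv_death = p_noncv
  )
  tab$p_stay <- 1 - tab$p_nonfatal_event - tab$p_fatal_event - tab$p_noncv_death
  if (any(tab$p_stay < -1e-12) ||
      any(tab[, c("p_nonfatal_event", "p_fatal_event", "p_noncv_death")] < 0) ||
      any(tab[, c("p_nonfatal_event", "p_fatal_event", "p_noncv_death")] > 1))
    abort("Transition probabilities escape [0, 1].", class = "prscea_domain_error")

  attr(tab, "stratum") <- stratum
  attr(tab, "arm") <- arm
  attr(tab, "intervention_active") <- intervention_active
  attr(tab, "statin_active") <- statin_active
  attr(tab, "entry_age") <- entry_age
  attr(tab, "end_age") <- end_age
  class(tab) <- c("transition_table", class(tab))
  tab
}

#' Propagate a cohort through a transition table
#'
#' Starts the cohort 100% event-free at the entry age and applies the annual
#' transition probabilities cycle by cycle. From `event_free`, individuals
#' may have a nonfatal event (to `post_event`), a fatal event (to
#' `cv_death`), die of non-CV causes, or remain event-free; `post_event`
#' individuals face the same non-CV mortality but no recurrent events; death
#' states are absorbing. Mass is conserved at every cycle.
#'
#' @param table A `transition_table`.
#' @return A `cohort_trace` tibble with columns `cycle`, `age`, and the four
#'   state occupancies (fractions summing to 1).
#' @export
run_cohort_trace <- function(table) {
  entry_age <- attr(table, "entry_age") %||% table$age[1L]
  n <- nrow(table)
  occ <- matrix(0, nrow = n + 1L, ncol = 4L,
                dimnames = list(NULL, health_states))
  occ[1L, "event_free"] <- 1
  for (t in seq_len(n)) {
    ef <- occ[t, "event_free"]; pe <- occ[t, "post_event"]
    pnf <- table$p_nonfatal_event[t]; pf <- table$p_fatal_event[t]
    pnc <- table$p_noncv_death[t]
    occ[t + 1L, "event_free"] <- ef * (1 - pnf - pf - pnc)
    occ[t + 1L, "post_event"] <- pe * (1 - pnc) + ef * pnf
    occ[t + 1L, "cv_death"] <- occ[t, "cv_death"] + ef * pf
    occ[t + 1L, "noncv_death"] <- occ[t, "noncv_death"] + (ef + pe) * pnc
  }
  out <- tibble::as_tibble(as.data.frame(occ))
  out <- dplyr::bind_cols(
    tibble::tibble(cycle = 0:n, age = entry_age + 0:n), out)
  attr(out, "entry_age") <- entry_age
  attr(out, "stratum") <- attr(table, "stratum")
  attr(out, "arm") <- attr(table, "arm")
  class(out) <- c("cohort_trace", class(out))
  out
}

# Age-banded utility weight.
utility_at_age <- function(params, age) {
  u <- param_value(params, c("utility_10_40", "utility_40_60", "utility_60plus"))
  ifelse(age < 40, u[1L], ifelse(age < 60, u[2L], u[3L]))
}

#' Life expectancy and discounted QALYs from a cohort trace
#'
#' Rewards are credited to the state occupied during each annual cycle
#' (occupancy at cycle start): life expectancy is the entry age plus the
#' undiscounted expected years alive; QALYs weight each alive year by the
#' age-banded utility and discount it at `discount_rate` with the first
#' cycle undiscounted. `post_event` years may be down-weighted via
#' `post_event_utility_multiplier` (default 1: the base case carries no
#' extra event disutility, because per-case QALY impacts enter the economic
#' ledger through fixed per-case quantities).
#'
#' @param trace A `cohort_trace`.
#' @param params A `parameter_set` (utilities and discount rate).
#' @param post_event_utility_multiplier Multiplier in \[0, 1\] applied to the
#'   utility of post-event years. Default 1.
#' @return A one-row tibble: `life_expectancy`, `life_years`,
#'   `discounted_life_years`, `qalys`, `discounted_qalys`.
#' @export
summarize_trace <- function(trace, params, post_event_utility_multiplier = 1) {
  entry_age <- attr(trace, "entry_age") %||% trace$age[1L]
  n <- nrow(trace) - 1L
  idx <- seq_len(n) # occupancy at the start of each of the n cycles
  alive <- trace$event_free[idx] + trace$post_event[idx]
  weighted <- trace$event_free[idx] +
    trace$post_event[idx] * post_event_utility_multiplier
  age <- trace$age[idx]
  u <- utility_at_age(params, age)
  r <- param_value(params, "discount_rate")
  disc <- (1 + r)^-(idx - 1L)
  tibble::tibble(
    life_expectancy = entry_age + sum(alive),
    life_years = sum(alive),
    discounted_life_years = sum(alive * disc),
    qalys = sum(weighted * u),
    discounted_qalys = sum(weighted * u * disc)
  )
}

#' Differences between two clinical scenario profiles
#'
#' Element-wise deltas and fold changes between a reference scenario and a
#' comparator (e.g. high-PRS without prevention vs. with prevention), for
#' the profile metrics life expectancy, QALYs, and 10-year MI / stroke /
#' fatal-MI risks.
#'
#' @param reference,comparator One-row data frames (or named lists) with
#'   columns `life_expectancy`, `qalys`, `mi_risk`, `stroke_risk`, `fatal_mi`.
#' @return A tibble with one row per metric: `reference`, `comparator`,
#'   `delta` (comparator - reference) and `fold_change` (comparator / reference).
#' @examples
#' sc <- scenario_fixtures()
#' project_scenario_delta(sc[sc$name == "high_prs_no_prevention", ],
#'                        sc[sc$name == "high_prs_with_prevention", ])
#' @export
project_scenario_delta <- function(reference, comparator) {
  metrics <- c("life_expectancy", "qalys", "mi_risk", "stroke_risk", "fatal_mi")
  ref <- vapply(metrics, function(m) as.numeric(reference[[m]]), numeric(1L))
  cmp <- vapply(metrics, function(m) as.numeric(comparator[[m]]), numeric(1L))
  tibble::tibble(
    metric = metrics,
    reference = unname(ref),
    comparator = unname(cmp),
    delta = unname(cmp - ref),
    fold_change = unname(ifelse(ref == 0, NA_real_, cmp / ref))
  )
}

#' Export a cohort trace as CSV
#'
#' Writes cycle, age, the four state occupancies, and cumulative discounted
#' life years and QALYs (credited per cycle as in [summarize_trace()]).
#'
#' @param trace A `cohort_trace`.
#' @param params A `parameter_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, params, path) {
  n <- nrow(trace) - 1L
  idx <- seq_len(n)
  alive <- trace$event_free[idx] + trace$post_event[idx]
  u <- utility_at_age(params, trace$age[idx])
  r <- param_value(params, "discount_rate")
  disc <- (1 + r)^-(idx - 1L)
  out <- as.data.frame(trace)
  out$cum_discounted_ly <- c(0, cumsum(alive * disc))
  out$cum_discounted_qaly <- c(0, cumsum(alive * u * disc))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Plot state occupancy over time for a cohort trace
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(health_states),
                              names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state, levels = health_states)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age (years)", y = "Cohort fraction", colour = "State") +
    ggplot2::theme_minimal()
}
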