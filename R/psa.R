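# Probabilistic sensitivity analysis -----------------------------------------

#' Run the Monte Carlo probabilistic sensitivity analysis
#'
#' Draws `n` realizations of every non-fixed parameter (beta incidences and
#' fatalities, the lognormal relative risk, gamma costs, normal utilities
#' and QALY losses), recomputes the full benefit ledger for each draw, and
#' summarizes every ledger field by its mean and empirical 2.5/97.5
#' percentiles. One RNG stream seeded once drives all draws in a fixed
#' parameter order, so identical `(params, n, seed)` reproduce the result
#' bit for bit; with all-fixed parameters every draw equals the
#' deterministic base case.
#'
#' @param params A `parameter_set`.
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid (USD/QALY) for the
#'   cost-effectiveness acceptability curve. Default $0–$100,000 in $1,000
#'   steps.
#' @param medication_pv Medication present-value convention, see
#'   [program_cost()].
#' @return A `psa_result`: list with `draws` (tibble, one row per draw),
#'   `summaries` (mean and percentile interval per field), `ceac` (tibble
#'   `wtp`, `probability`), `n_draws`, `seed`, and the base-case `icer`.
#' @examples
#' psa <- run_psa(default_parameters(), n = 100, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(params, n = 1000, seed = 1,
                    wtp_grid = seq(0, 100000, by = 1000),
                    medication_pv = c("printed", "annuity")) {
  medication_pv <- match.arg(medication_pv)
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.", class = "prscea_domain_error")
  validate_parameter_set(params)
  set.seed(seed)
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    draws[[i]] <- tryCatch(
      ledger_values(draw_parameters(params), medication_pv),
      error = function(e) abort(paste0("PSA draw ", i, " failed: ",
                                       conditionMessage(e)),
                                class = "prscea_psa_error")
    )
  }
  mat <- do.call(rbind, draws)
  draws_tbl <- tibble::as_tibble(as.data.frame(mat))
  draws_tbl$draw <- seq_len(n)
  draws_tbl <- dplyr::relocate(draws_tbl, "draw")

  fields <- colnames(mat)
  summaries <- tibble::tibble(
    field = fields,
    mean = unname(colMeans(mat)),
    p2.5 = unname(apply(mat, 2L, quantile, probs = 0.025, names = FALSE)),
    p97.5 = unname(apply(mat, 2L, quantile, probs = 0.975, names = FALSE))
  )

  base <- ledger_values(params, medication_pv)
  out <- structure(
    list(draws = draws_tbl, summaries = summaries, n_draws = n, seed = seed,
         icer = unname(base[["icer"]]), wtp_grid = wtp_grid, ceac = NULL),
    class = "psa_result")
  out$ceac <- ceac_curve(out, wtp_grid)
  out
}

#' Net monetary benefit
#'
#' `wtp * delta_qalys - delta_cost`: positive at a given willingness-to-pay
#' threshold means the intervention is cost-effective there.
#'
#' @param delta_qalys Incremental QALYs.
#' @param delta_cost Incremental cost (USD).
#' @param wtp Willingness to pay (USD/QALY).
#' @return Net monetary benefit (USD).
#' @export
nmb <- function(delta_qalys, delta_cost, wtp) {
  wtp * delta_qalys - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws whose net
#' monetary benefit (QALYs gained valued at WTP, minus program cost) is
#' positive.
#'
#' @param result A `psa_result`.
#' @param wtp_grid Ascending willingness-to-pay grid (USD/QALY).
#' @return A tibble with columns `wtp` and `probability`.
#' @export
ceac_curve <- function(result, wtp_grid = result$wtp_grid) {
  if (length(wtp_grid) == 0L || is.unsorted(wtp_grid))
    abort("`wtp_grid` must be nonempty and ascending.",
          class = "prscea_domain_error")
  q <- result$draws$qalys
  cost <- result$draws$program_cost
  prob <- vapply(wtp_grid, function(w) mean(nmb(q, cost, w) > 0), numeric(1L))
  tibble::tibble(wtp = wtp_grid, probability = prob)
}

#' Probability the program is cost-effective at a threshold
#'
#' @param result A `psa_result`.
#' @param wtp Willingness-to-pay threshold (USD/QALY), default $50,000.
#' @return Fraction of draws with positive net monetary benefit.
#' @export
prob_cost_effective <- function(result, wtp = 50000) {
  mean(nmb(result$draws$qalys, result$draws$program_cost, wtp) > 0)
}

#' @export
print.psa_result <- function(x, ...) {
  s <- x$summaries
  pick <- function(f) s[s$field == f, ]
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %d)\n",
              x$n_draws, x$seed))
  for (f in c("events", "qalys", "roi_pct")) {
    r <- pick(f)
    cat(sprintf("  %-18s mean %10.1f  [%.1f, %.1f]\n", f, r$mean, r$p2.5, r$p97.5))
  }
  cat(sprintf("  P(cost-effective at $50,000/QALY) = %.3f\n",
              prob_cost_effective(x)))
  invisible(x)
}

#' Tidy PSA summaries
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble of per-field mean and 2.5/97.5 percentiles.
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$summaries

#' One-row PSA summary
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return One-row tibble: draws, seed, mean events, mean QALYs, mean ROI,
#'   ICER, and probability cost-effective at $50,000/QALY.
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  m <- setNames(x$summaries$mean, x$summaries$field)
  tibble::tibble(
    n_draws = x$n_draws, seed = x$seed,
    mean_events = unname(m[["events"]]),
    mean_qalys = unname(m[["qalys"]]),
    mean_roi_pct = unname(m[["roi_pct"]]),
    icer = x$icer,
    prob_ce_50k = prob_cost_effective(x, 50000)
  )
}

#' Plot the cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness against willingness to pay, with a
#' vertical marker at the base-case ICER.
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$icer, linetype = "dashed",
                        colour = "purple") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Export PSA draws, summaries, or the CEAC as CSV
#'
#' @param result A `psa_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psa_draws_csv <- function(result, path) {
  write.csv(as.data.frame(result$draws), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_draws_csv
#' @export
write_psa_summary_csv <- function(result, path) {
  write.csv(as.data.frame(result$summaries), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa_draws_csv
#' @export
write_ceac_csv <- function(result, path) {
  write.csv(as.data.frame(result$ceac), path, row.names = FALSE)
  invisible(path)
}
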