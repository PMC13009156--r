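# Country-level localization --------------------------------------------------

#' Localize ICER and ROI with a country cost/benefit profile
#'
#' Scales program costs by `cost_factor` and monetized benefits by
#' `benefit_factor`:
#' `ICER = cost_factor * program_cost / QALYs gained` and
#' `ROI% = 100 * (benefit_factor * total_benefit - cost_factor * cost) /
#' (cost_factor * cost)`. The identity profile (1, 1) reproduces the base
#' ledger.
#'
#' @param ledger A `benefit_ledger`.
#' @param cost_factor,benefit_factor Positive scaling factors.
#' @param country Optional country label carried into the output.
#' @return One-row tibble: `country`, `cost_factor`, `benefit_factor`,
#'   `icer`, `roi_pct`.
#' @examples
#' led <- benefit_ledger(default_parameters())
#' apply_country_profile(led, 0.75, 0.65, "UK")
#' @export
apply_country_profile <- function(ledger, cost_factor, benefit_factor,
                                  country = NA_character_) {
  if (!is.numeric(cost_factor) || !is.numeric(benefit_factor) ||
      cost_factor <= 0 || benefit_factor <= 0)
    abort("Scaling factors must be positive.", class = "prscea_domain_error")
  v <- ledger$values
  cost <- cost_factor * v[["program_cost"]]
  benefit <- benefit_factor * v[["total_benefit"]]
  tibble::tibble(
    country = country,
    cost_factor = cost_factor,
    benefit_factor = benefit_factor,
    icer = cost / v[["qalys"]],
    roi_pct = 100 * (benefit - cost) / cost
  )
}

#' Country table of localized ICER and ROI estimates
#'
#' Applies each row of a country profile table to the base ledger.
#'
#' @param ledger A `benefit_ledger`.
#' @param profiles Tibble with columns `country`, `cost_factor`,
#'   `benefit_factor` (default [country_profiles()], the reconstructed
#'   factors).
#' @return A tibble with one row per country.
#' @export
localize_ledger <- function(ledger, profiles = country_profiles()) {
  purrr::pmap_dfr(profiles, function(country, cost_factor, benefit_factor)
    apply_country_profile(ledger, cost_factor, benefit_factor, country))
}
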