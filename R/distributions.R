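# Distribution specifications ------------------------------------------------
#
# Each model parameter carries one of five distribution kinds used by the
# probabilistic sensitivity analysis:
#   beta         par1 = alpha, par2 = beta          (proportions)
#   gamma        par1 = shape, par2 = scale         (costs)
#   normal       par1 = mean,  par2 = sd            (utilities, QALY losses)
#   lognormal_rr par1 = meanlog, par2 = sdlog of a relative risk RR; the
#                parameter value drawn is 1 - RR (a relative risk REDUCTION),
#                so the median of the drawn value equals the base value
#   fixed        par1 = value                       (not varied)

dist_kinds <- c("beta", "gamma", "normal", "lognormal_rr", "fixed")

#' Gamma hyperparameters from a mean and coefficient of variation
#'
#' Cost parameters are specified in the literature as a mean with a
#' coefficient of variation (CV = sd/mean). For a gamma distribution this
#' pins down shape = 1/CV^2 and scale = mean * CV^2.
#'
#' @param mean Positive mean of the distribution (e.g. USD).
#' @param cv Positive coefficient of variation (sd/mean).
#' @return A named list with elements `shape` and `scale`.
#' @examples
#' gamma_from_mean_cv(400, 0.20) # shape 25, scale 16
#' @export
gamma_from_mean_cv <- function(mean, cv) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    abort("`mean` must be a single positive number.", class = "prscea_domain_error")
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv <= 0)
    abort("`cv` must be a single positive number.", class = "prscea_domain_error")
  list(shape = 1 / cv^2, scale = mean * cv^2)
}

#' Lognormal relative-risk hyperparameters from a median and 95% interval
#'
#' Parameterizes a lognormal distribution for a relative risk (RR) from its
#' median and a 95% uncertainty interval: `meanlog = log(median)` and
#' `sdlog = log(high/low) / (2 * 1.96)`.
#'
#' @param median Median relative risk, in (0, 1).
#' @param ci_low,ci_high 95% interval bounds with `0 < ci_low < median < ci_high`.
#' @return A named list with elements `meanlog` and `sdlog`.
#' @examples
#' lognormal_rr_from_ci(0.70, 0.60, 0.80)
#' @export
lognormal_rr_from_ci <- function(median, ci_low, ci_high) {
  ok <- is.numeric(median) && is.numeric(ci_low) && is.numeric(ci_high) &&
    all(is.finite(c(median, ci_low, ci_high)))
  if (!ok || !(0 < ci_low && ci_low < median && median < ci_high) || median >= 1)
    abort("Require 0 < ci_low < median < ci_high, with the median in (0, 1).",
          class = "prscea_domain_error")
  list(meanlog = log(median), sdlog = log(ci_high / ci_low) / (2 * qnorm(0.975)))
}

# Central value implied by a distribution row: the mean for beta/gamma/normal
# and fixed, the MEDIAN of 1 - RR for lognormal_rr (its mean has no closed
# role in the model; the base value anchors the median).
dist_central <- function(kind, par1, par2) {
  switch(kind,
    beta = par1 / (par1 + par2),
    gamma = par1 * par2,
    normal = par1,
    lognormal_rr = 1 - exp(par1),
    fixed = par1,
    abort(paste0("Unknown distribution kind: ", kind))
  )
}

# One random draw from a distribution row. Normal draws are truncated by
# resampling (not clipping) to the admissible range implied by the units:
# utilities and probabilities to [0, 1], everything else to [0, Inf).
dist_draw <- function(kind, par1, par2, units) {
  switch(kind,
    fixed = par1,
    beta = rbeta(1L, par1, par2),
    gamma = rgamma(1L, shape = par1, scale = par2),
    lognormal_rr = 1 - rlnorm(1L, meanlog = par1, sdlog = par2),
    normal = {
      upper <- if (units %in% c("utility", "probability", "fraction")) 1 else Inf
      repeat {
        x <- rnorm(1L, mean = par1, sd = par2)
        if (x >= 0 && x <= upper) break
      }
      x
    },
    abort(paste0("Unknown distribution kind: ", kind))
  )
}
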