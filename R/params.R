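# Parameter registry ---------------------------------------------------------

#' Required parameter names
#'
#' Every parameter set must carry these names exactly once; additional
#' parameters (e.g. the screening-schedule constants) are permitted.
#'
#' @return Character vector of required parameter names.
#' @export
required_parameter_names <- function() {
  c(
    "cad_incidence_10y_top20", "stroke_incidence_10y_top20",
    "relative_risk_reduction",
    "utility_10_40", "utility_40_60", "utility_60plus",
    "cad_fatality", "stroke_fatality",
    "qaly_loss_fatal_cad", "qaly_loss_fatal_stroke",
    "genetic_test_cost", "statin_monitoring_annual_cost",
    "lifetime_cad_cost", "lifetime_stroke_cost",
    "discount_rate", "medical_inflation",
    "qaly_monetary_value", "productivity_per_case",
    "cobenefit_multiplier", "qaly_gain_per_case",
    "cohort_size", "high_risk_fraction", "very_high_risk_fraction",
    "horizon_years"
  )
}

param_columns <- c("name", "base_value", "units", "kind", "par1", "par2", "note")

#' Construct and validate a parameter set
#'
#' A parameter set is a tibble with one row per model input: `name`,
#' `base_value`, `units`, distribution `kind` and hyperparameters
#' `par1`/`par2` (see [gamma_from_mean_cv()] and [lognormal_rr_from_ci()] for
#' the cost and relative-risk parameterizations), and a free-text `note`.
#' Validation enforces ranges by units (probabilities, fractions and
#' utilities in \[0, 1\]; costs and QALYs nonnegative), rate bounds, the
#' risk-tier ordering, and consistency of each distribution with its base
#' value (mean for beta/gamma/normal, median for `lognormal_rr`).
#'
#' @param x A data frame with the columns listed above (`par2` and `note`
#'   may be omitted; they default to `NA`).
#' @return A validated `parameter_set` tibble.
#' @seealso [default_parameters()], [load_parameter_set()], [sample_draw()]
#' @export
parameter_set <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"par2" %in% names(x)) x$par2 <- NA_real_
  if (!"note" %in% names(x)) x$note <- NA_character_
  missing_cols <- setdiff(setdiff(param_columns, c("par2", "note")), names(x))
  if (length(missing_cols) > 0L)
    abort(paste0("Parameter set is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "prscea_validation_error")
  x <- x[param_columns]
  x$base_value <- as.numeric(x$base_value)
  x$par1 <- as.numeric(x$par1)
  x$par2 <- as.numeric(x$par2)
  class(x) <- c("parameter_set", class(x))
  validate_parameter_set(x)
  x
}

#' Validate a parameter set against the model's invariants
#'
#' @param params A `parameter_set` (or coercible data frame).
#' @return `params`, invisibly; errors describe the offending parameter.
#' @export
validate_parameter_set <- function(params) {
  p <- tibble::as_tibble(params)

  dup <- p$name[duplicated(p$name)]
  if (length(dup) > 0L)
    abort(paste0("Duplicate parameter name(s): ", paste(unique(dup), collapse = ", ")),
          class = "prscea_validation_error")
  absent <- setdiff(required_parameter_names(), p$name)
  if (length(absent) > 0L)
    abort(paste0("Missing required parameter(s): ", paste(absent, collapse = ", ")),
          class = "prscea_validation_error")

  bad_kind <- setdiff(unique(p$kind), dist_kinds)
  if (length(bad_kind) > 0L)
    abort(paste0("Unknown distribution kind(s): ", paste(bad_kind, collapse = ", ")),
          class = "prscea_validation_error")

  for (i in seq_len(nrow(p))) {
    row <- p[i, ]
    nm <- row$name
    fail <- function(msg) abort(paste0("Parameter `", nm, "`: ", msg),
                                class = "prscea_range_error")
    if (!is.finite(row$base_value)) fail("base_value must be finite.")
    if (row$units %in% c("probability", "fraction", "utility")) {
      if (row$base_value < 0 || row$base_value > 1)
        fail("value must lie in [0, 1].")
    } else if (row$base_value < 0) {
      fail("value must be nonnegative.")
    }
    if (nm %in% c("discount_rate", "medical_inflation") &&
        (row$base_value < 0 || row$base_value > 0.2))
      fail("rate must lie in [0, 0.2].")

    switch(row$kind,
      beta = {
        if (!is.finite(row$par1) || !is.finite(row$par2) ||
            row$par1 <= 0 || row$par2 <= 0)
          fail("beta requires alpha > 0 and beta > 0.")
      },
      gamma = {
        if (!is.finite(row$par1) || !is.finite(row$par2) ||
            row$par1 <= 0 || row$par2 <= 0)
          fail("gamma requires shape > 0 and scale > 0.")
      },
      normal = {
        if (!is.finite(row$par2) || row$par2 <= 0)
          fail("normal requires sd > 0.")
      },
      lognormal_rr = {
        rr <- exp(row$par1)
        if (!is.finite(row$par2) || row$par2 <= 0 || rr <= 0 || rr >= 1)
          fail("lognormal_rr requires sdlog > 0 and median RR in (0, 1).")
      },
      fixed = NULL
    )
    if (row$kind != "fixed") {
      central <- dist_central(row$kind, row$par1, row$par2)
      if (abs(central - row$base_value) > 1e-9 * max(1, abs(row$base_value)))
        fail(sprintf("distribution central value %.10g does not match base_value %.10g.",
                     central, row$base_value))
    } else if (abs(row$par1 - row$base_value) > 0) {
      fail("fixed distribution value must equal base_value.")
    }
  }

  hi <- p$base_value[p$name == "high_risk_fraction"]
  vhi <- p$base_value[p$name == "very_high_risk_fraction"]
  if (!(hi >= vhi && vhi > 0))
    abort("Require high_risk_fraction >= very_high_risk_fraction > 0.",
          class = "prscea_range_error")

  invisible(params)
}

#' Look up base values of parameters by name
#'
#' @param params A `parameter_set`.
#' @param name Character vector of parameter names.
#' @param default Value returned for names not present (default: error).
#' @return Numeric vector of base values.
#' @export
param_value <- function(params, name, default = NULL) {
  idx <- match(name, params$name)
  if (anyNA(idx)) {
    if (!is.null(default)) {
      out <- params$base_value[idx]
      out[is.na(idx)] <- default
      return(unname(out))
    }
    abort(paste0("Unknown parameter(s): ", paste(name[is.na(idx)], collapse = ", ")),
          class = "prscea_validation_error")
  }
  unname(params$base_value[idx])
}

# YAML hyperparameter field names per kind.
dist_field_names <- list(
  beta = c("alpha", "beta"),
  gamma = c("shape", "scale"),
  normal = c("mean", "sd"),
  lognormal_rr = c("meanlog", "sdlog"),
  fixed = c("value", NA_character_)
)

#' Read a parameter set from its YAML configuration format
#'
#' The configuration dialect is a YAML document with a top-level `parameters`
#' list; each entry has `name`, `base_value`, `units`, a `distribution`
#' mapping (`kind` plus kind-specific hyperparameters: `alpha`/`beta`,
#' `shape`/`scale`, `mean`/`sd`, `meanlog`/`sdlog`, or `value`), and an
#' optional `note`. Writing with [write_parameter_set()] and re-reading
#' reproduces every numeric field exactly.
#'
#' @param path Path to a YAML configuration file.
#' @param text YAML text given directly (overrides `path`).
#' @return A validated `parameter_set`.
#' @export
load_parameter_set <- function(path = NULL, text = NULL) {
  doc <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (!is.list(doc) || is.null(doc$parameters))
    abort("Configuration must contain a top-level `parameters` list.",
          class = "prscea_validation_error")
  rows <- purrr::map(doc$parameters, function(e) {
    for (f in c("name", "base_value", "units", "distribution"))
      if (is.null(e[[f]]))
        abort(paste0("Parameter entry", if (!is.null(e$name)) paste0(" `", e$name, "`"),
                     " is missing field `", f, "`."),
              class = "prscea_validation_error")
    kind <- e$distribution$kind
    if (is.null(kind) || !kind %in% dist_kinds)
      abort(paste0("Parameter `", e$name, "`: unknown or missing distribution kind."),
            class = "prscea_validation_error")
    fields <- dist_field_names[[kind]]
    par1 <- e$distribution[[fields[[1L]]]]
    if (is.null(par1))
      abort(paste0("Parameter `", e$name, "`: distribution is missing `",
                   fields[[1L]], "`."), class = "prscea_validation_error")
    par2 <- if (is.na(fields[[2L]])) NA_real_ else e$distribution[[fields[[2L]]]]
    if (!is.na(fields[[2L]]) && is.null(par2))
      abort(paste0("Parameter `", e$name, "`: distribution is missing `",
                   fields[[2L]], "`."), class = "prscea_validation_error")
    tibble::tibble(
      name = e$name, base_value = as.numeric(e$base_value), units = e$units,
      kind = kind, par1 = as.numeric(par1), par2 = as.numeric(par2),
      note = if (is.null(e$note)) NA_character_ else e$note
    )
  })
  parameter_set(dplyr::bind_rows(rows))
}

#' Write a parameter set to the YAML configuration format
#'
#' @param params A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  validate_parameter_set(params)
  entries <- purrr::pmap(params, function(name, base_value, units, kind, par1, par2, note) {
    fields <- dist_field_names[[kind]]
    dist <- setNames(list(kind), "kind")
    dist[[fields[[1L]]]] <- par1
    if (!is.na(fields[[2L]])) dist[[fields[[2L]]]] <- par2
    e <- list(name = name, base_value = base_value, units = units, distribution = dist)
    if (!is.na(note)) e$note <- note
    e
  })
  yaml::write_yaml(list(parameters = entries), path, precision = 17L)
  invisible(path)
}

#' Export a parameter set as a flat CSV audit table
#'
#' One row per parameter: name, base value, units, distribution kind and
#' hyperparameters.
#'
#' @param params A `parameter_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_csv <- function(params, path) {
  validate_parameter_set(params)
  write.csv(as.data.frame(params[param_columns]), path, row.names = FALSE)
  invisible(path)
}

# One realization of every parameter, without touching the RNG seed.
# Draw order is the row order of `params`, one stream, so seeds are portable.
draw_parameters <- function(params) {
  out <- params
  for (i in seq_len(nrow(params))) {
    if (params$kind[i] == "fixed") next
    out$base_value[i] <- dist_draw(params$kind[i], params$par1[i],
                                   params$par2[i], params$units[i])
  }
  out
}

#' Draw one probabilistic-sensitivity-analysis realization of a parameter set
#'
#' Replaces each non-fixed parameter's base value by one random draw from its
#' distribution (fixed parameters are untouched). Normal draws are truncated
#' by resampling: utilities to \[0, 1\], QALY losses to \[0, Inf). Draws are
#' taken in row order from a single RNG stream seeded with `seed`, so the
#' same seed reproduces the same realization bit for bit.
#'
#' @param params A `parameter_set`.
#' @param seed Integer seed.
#' @return A `parameter_set` with sampled base values (distribution columns
#'   are carried along unchanged for reference).
#' @export
sample_draw <- function(params, seed) {
  validate_parameter_set(params)
  set.seed(seed)
  draw_parameters(params)
}
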