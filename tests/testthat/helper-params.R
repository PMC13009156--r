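# Shared fixtures for the test suite -----------------------------------------

# Degenerate version of a parameter set: every distribution collapsed to a
# point mass at its base value.
make_all_fixed <- function(params = default_parameters()) {
  params$kind <- "fixed"
  params$par1 <- params$base_value
  params$par2 <- NA_real_
  validate_parameter_set(params)
  params
}

# Replace one parameter by a fixed value (used to switch off stroke hazard,
# zero the discount rate, pin utilities, etc.).
set_fixed <- function(params, name, value) {
  i <- match(name, params$name)
  stopifnot(!is.na(i))
  params$base_value[i] <- value
  params$kind[i] <- "fixed"
  params$par1[i] <- value
  params$par2[i] <- NA_real_
  params
}
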