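# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, hand arithmetic and closed forms.

# two-draw enumeration over {15N, 14N}^2: the pairing distribution follows
# from listing all four ordered atom pairs with their probabilities
enumerate_pairing <- function(f) {
  atoms <- c(heavy = f, light = 1 - f)
  joint <- outer(atoms, atoms)
  c(
    heavy = joint["heavy", "heavy"],
    mixed = joint["heavy", "light"] + joint["light", "heavy"],
    light = joint["light", "light"]
  )
}

# hand OLS slope: sum((x - xbar)(y - ybar)) / sum((x - xbar)^2)
ols_slope_by_hand <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# dimensionless Henry constant from first principles: van 't Hoff-corrected
# solubility times RT (reference solubilities restated independently here)
henry_cc_by_hand <- function(species, temp_c) {
  ref <- list(
    N2O = list(hcp = 0.025, vh = 2700),
    N2 = list(hcp = 6.4e-4, vh = 1300)
  )[[species]]
  t_k <- temp_c + 273.15
  hcp_t <- ref$hcp * exp(ref$vh * (1 / t_k - 1 / 298.15))
  hcp_t * 0.08205736 * t_k
}

# a minimal long-format time-series tibble for slope-fitting tests
series_tbl <- function(time_h, value, species = "30N2") {
  tibble::tibble(
    time_h = time_h, species = species, total_umol = value
  )
}

# default study conditions used by end-to-end tests
study_config <- function(...) vial_config(...)

noise_free_params <- function(rates, seed = 1L, ...) {
  sim_params(rates = rates, noise_cv = 0, n_replicates = 1, seed = seed, ...)
}

# random but physically feasible rate draws for property tests:
# C_nitrite <= P (nitrite-derived N2O cannot be consumed faster than made)
# and the exogenous pool outlasts the incubation at the default spike
draw_feasible_rates <- function(n) {
  tibble::tibble(
    anammox = stats::runif(n, 0.2, 1.2),
    n2o_production = stats::runif(n, 0.005, 0.1),
    n2o_consumption_nitrite = stats::runif(n, 0, 1) * n2o_production,
    n2o_consumption_exo = stats::runif(n, 0, 0.25)
  )
}
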