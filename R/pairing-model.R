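#' Binomial pairing probabilities for a partially labelled nitrogen pool
#'
#' When two nitrogen atoms are drawn at random from a nitrite pool containing
#' a fraction `f` of heavy (15N) atoms, the product molecule (N2 via
#' denitrification-derived N2O, or N2O itself) is heavy-heavy with
#' probability f^2, mixed with probability 2f(1-f), and light-light with
#' probability (1-f)^2. These three numbers drive every isotopologue
#' prediction in the forward model.
#'
#' @param f Fraction of 15N in the nitrite pool; scalar in (0, 1].
#'   Default 0.98, the labelling grade of commercial 15N-nitrite stocks.
#'
#' @return A one-row tibble with columns `p_heavy` (-> 46N2O / 30N2),
#'   `p_mixed` (-> 45N2O / 29N2) and `p_light` (-> 44N2O / 28N2).
#'   The three sum to one.
#'
#' @examples
#' pairing_probabilities(0.98)
#' pairing_probabilities(1)   # fully labelled: only heavy products
#' @export
pairing_probabilities <- function(f = 0.98) {
  check_label_fraction(f)
  tibble(
    p_heavy = f^2,
    p_mixed = 2 * f * (1 - f),
    p_light = (1 - f)^2
  )
}

check_label_fraction <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0 || f > 1) {
    abort("`f` must be a single number in (0, 1].", class = "n2opair_domain_error")
  }
  invisible(f)
}

#' Process-rate set for a tracer incubation
#'
#' Bundles the four biomass-specific rates that generate gas in a sealed
#' vial: `anammox` (N2 production pairing one nitrite N with one ammonium N),
#' `n2o_production` (denitrification of nitrite to N2O),
#' `n2o_consumption_nitrite` (further reduction of nitrite-derived N2O to
#' N2) and `n2o_consumption_exo` (reduction of the exogenous, unlabelled
#' N2O spike to N2). All rates are in mg N per g biomass per hour, counting
#' every N atom in the product molecule.
#'
#' @param anammox,n2o_production,n2o_consumption_nitrite,n2o_consumption_exo
#'   Non-negative scalars, mg N g^-1 h^-1.
#'
#' @return A list of class `process_rates` with the four fields plus
#'   `n2o_consumption_total` (the sum of the two consumption terms).
#' @examples
#' process_rates(anammox = 0.9, n2o_production = 0.037,
#'               n2o_consumption_nitrite = 0.02, n2o_consumption_exo = 0.19)
#' @export
process_rates <- function(anammox = 0,
                          n2o_production = 0,
                          n2o_consumption_nitrite = 0,
                          n2o_consumption_exo = 0) {
  vals <- c(
    anammox = anammox, n2o_production = n2o_production,
    n2o_consumption_nitrite = n2o_consumption_nitrite,
    n2o_consumption_exo = n2o_consumption_exo
  )
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0)) {
    abort("All process rates must be non-negative numbers.",
      class = "n2opair_domain_error"
    )
  }
  structure(
    list(
      anammox = anammox,
      n2o_production = n2o_production,
      n2o_consumption_nitrite = n2o_consumption_nitrite,
      n2o_consumption_exo = n2o_consumption_exo,
      n2o_consumption_total = n2o_consumption_nitrite + n2o_consumption_exo
    ),
    class = "process_rates"
  )
}

#' @export
print.process_rates <- function(x, ...) {
  cat("<process_rates> (mg N g^-1 h^-1)\n")
  cat(sprintf("  anammox:                  %g\n", x$anammox))
  cat(sprintf("  N2O production:           %g\n", x$n2o_production))
  cat(sprintf("  N2O consumption (NO2-):   %g\n", x$n2o_consumption_nitrite))
  cat(sprintf("  N2O consumption (exo):    %g\n", x$n2o_consumption_exo))
  invisible(x)
}

#' Forward model: net isotopologue production rates
#'
#' Maps the four process rates to net production rates of the six gas
#' isotopologues under random binomial pairing at label fraction `f`, with
#' consumption of nitrite-derived N2O removing isotopologues in the same
#' binomial proportions in which they are produced (the source-proportional
#' assumption under which the slope-inversion equations are exact):
#'
#' * `46N2O`: (P - Cn) f^2, `45N2O`: (P - Cn) 2f(1-f),
#'   `44N2O`: (P - Cn)(1-f)^2 - Cx
#' * `30N2`: Cn f^2, `29N2`: A f + Cn 2f(1-f),
#'   `28N2`: A (1-f) + Cn (1-f)^2 + Cx
#'
#' where A = anammox, P = N2O production, Cn / Cx = consumption of
#' nitrite-derived / exogenous N2O. Summed over all six species the
#' consumption terms cancel and the total equals A + P, the total nitrogen
#' entering the gas pool per hour.
#'
#' @param rates A [process_rates()] object (or list with the same fields).
#' @param f Label fraction of the nitrite pool, see
#'   [pairing_probabilities()].
#'
#' @return A tibble with columns `species` and `rate_mg_n_g_h` (signed net
#'   rate, mg N g^-1 h^-1), one row per isotopologue.
#' @examples
#' forward_species_rates(process_rates(anammox = 1), f = 1)
#' @export
forward_species_rates <- function(rates, f = 0.98) {
  check_label_fraction(f)
  if (!all(c("anammox", "n2o_production") %in% names(rates))) {
    abort("`rates` must be a process_rates() object.",
      class = "n2opair_domain_error"
    )
  }
  p <- pairing_probabilities(f)
  a <- rates$anammox
  prod <- rates$n2o_production
  cn <- rates$n2o_consumption_nitrite
  cx <- rates$n2o_consumption_exo
  net_n2o <- prod - cn
  tibble(
    species = SPECIES_ALL,
    rate_mg_n_g_h = c(
      a * (1 - f) + cn * p$p_light + cx, # 28N2
      a * f + cn * p$p_mixed, # 29N2
      cn * p$p_heavy, # 30N2
      net_n2o * p$p_light - cx, # 44N2O
      net_n2o * p$p_mixed, # 45N2O
      net_n2o * p$p_heavy # 46N2O
    )
  )
}
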