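#' Ordinary least-squares slope of one isotopologue over the analysis window
#'
#' Fits amount ~ time by OLS on the points whose times fall inside
#' `window` (endpoints inclusive). The default window, 4-15 h, skips the
#' equilibration transient at the start of the incubation.
#'
#' @param data A time-series tibble for one replicate (e.g. one replicate
#'   of [simulate_vial()] output) with columns `time_h`, `species` and the
#'   amount column named by `value_col`.
#' @param species Isotopologue to fit, one of `"28N2"`, `"29N2"`,
#'   `"30N2"`, `"44N2O"`, `"45N2O"`, `"46N2O"`.
#' @param window Numeric length-2, hours; points with
#'   `window[1] <= time_h <= window[2]` are used.
#' @param value_col Amount column to regress, default `"total_umol"`.
#'
#' @return An object of class `slope_fit`: a list with `slope` and
#'   `stderr` (umol h^-1), `intercept` (umol), `r_squared`, `n_points`,
#'   `window` and `species`. `tidy()` and `glance()` methods are
#'   available.
#' @examples
#' sim <- simulate_vial(vial_config(), sim_params(noise_cv = 0, seed = 1))
#' fit_slope(dplyr::filter(sim, replicate == 1), "30N2")
#' @export
fit_slope <- function(data, species, window = c(4, 15),
                      value_col = "total_umol") {
  sp <- species
  d <- data |>
    dplyr::filter(.data$species == sp,
      .data$time_h >= window[1], .data$time_h <= window[2]
    )
  if (nrow(d) < 3) {
    abort("Need at least 3 in-window points to fit a slope.",
      class = "n2opair_estimation_error"
    )
  }
  if (stats::var(d$time_h) == 0) {
    abort("Zero variance in time: cannot fit a slope.",
      class = "n2opair_estimation_error"
    )
  }
  y <- d[[value_col]]
  fit <- stats::lm(y ~ time_h, data = d)
  # summary.lm warns on exactly collinear (noise-free) input; harmless here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      stderr = unname(sm$coefficients[2, 2]),
      r_squared = sm$r.squared,
      n_points = nrow(d),
      window = window,
      species = sp
    ),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf(
    "<slope_fit> %s: %.5g umol/h (SE %.3g, r^2 %.4f, n=%d, window [%g, %g] h)\n",
    x$species, x$slope, x$stderr, x$r_squared, x$n_points,
    x$window[1], x$window[2]
  ))
  invisible(x)
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(
    species = x$species,
    slope_umol_h = x$slope,
    intercept_umol = x$intercept,
    std_error = x$stderr
  )
}

#' @export
glance.slope_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared, n_points = x$n_points,
    window_start_h = x$window[1], window_end_h = x$window[2]
  )
}

#' Reconstruct total vial amount from a headspace measurement
#'
#' At Henry equilibrium the total amount of a gas in the vial is the
#' headspace amount times `1 + H_cc * V_liquid / V_headspace`.
#'
#' @param headspace_umol Headspace amount(s), umol.
#' @param config A [vial_config()] supplying volumes and temperature.
#' @param species Gas species (isotopologue labels accepted).
#' @return Total amount(s), umol.
#' @examples
#' headspace_to_total(1, vial_config(), "44N2O")
#' @export
headspace_to_total <- function(headspace_umol, config, species) {
  hcc <- henry_cc(species, config$temperature_c)
  headspace_umol * (1 + hcc * config$v_liquid_ml / config$v_headspace_ml)
}

#' Convert a fitted slope to a biomass-specific rate
#'
#' Multiplies a molecular slope (umol of N2 or N2O per hour) by
#' 0.028 mg N per umol (two N atoms per molecule) and divides by the
#' catalytic biomass.
#'
#' @param slope_umol_h Fitted slope, umol h^-1 (signed).
#' @param biomass_g Catalytic biomass, g (MLVSS basis).
#' @param species Gas species; only N2/N2O isotopologues are supported.
#' @return Rate in mg N g^-1 h^-1.
#' @examples
#' normalize_slope(1, 0.3, "30N2")
#' @export
normalize_slope <- function(slope_umol_h, biomass_g, species) {
  parent_gas(species) # validates the species
  if (biomass_g <= 0) {
    abort("`biomass_g` must be positive.", class = "n2opair_domain_error")
  }
  slope_umol_h * MG_N_PER_UMOL_PAIR / biomass_g
}

#' Observed biomass-specific slopes for all four inversion isotopologues
#'
#' For each replicate in a vial time series, fits the 4-15 h OLS slope of
#' 29N2, 30N2, 44N2O and 46N2O and normalises it to mg N per g MLVSS per
#' hour. By default the regression uses total vial amounts reconstructed
#' from the measured headspace via Henry's law (`phase = "total"`); set
#' `phase = "headspace"` to fit raw headspace amounts only (a sensitivity
#' mode that understates rates by the dissolved fraction).
#'
#' @param data Output of [simulate_vial()] or [read_timeseries()]
#'   (columns `replicate`, `time_h`, `species`, `headspace_umol`).
#' @param config The [vial_config()] describing the vials; defaults to the
#'   `config` attribute of `data` when present.
#' @param window Slope window in hours, endpoints inclusive.
#' @param phase `"total"` (default) or `"headspace"`, see above.
#' @param mlvss_scale Extra multiplier on the biomass denominator
#'   (default 1), for normalisation-basis sensitivity analyses.
#'
#' @return A tibble with one row per replicate: `replicate`,
#'   `v_obs_29n2`, `v_obs_30n2`, `v_obs_44n2o`, `v_obs_46n2o`
#'   (mg N g^-1 h^-1; the 44N2O slope is normally negative), `biomass_g`,
#'   `f_label`. Per-slope [fit_slope()] diagnostics are attached as the
#'   `fits` attribute.
#' @examples
#' sim <- simulate_vial(vial_config(), sim_params(noise_cv = 0, seed = 1))
#' observed_slopes(sim)
#' @export
observed_slopes <- function(data, config = NULL, window = c(4, 15),
                            phase = c("total", "headspace"),
                            mlvss_scale = 1) {
  phase <- match.arg(phase)
  config <- config %||% attr(data, "config")
  if (is.null(config)) {
    abort("Provide `config`: the input carries no vial_config attribute.",
      class = "n2opair_domain_error"
    )
  }
  biomass <- biomass_mlvss_g(config) * mlvss_scale

  d <- as_tibble(data)
  if (phase == "total") {
    d$fit_value <- headspace_to_total(d$headspace_umol, config, d$species)
  } else {
    d$fit_value <- d$headspace_umol
  }

  targets <- c("29N2", "30N2", "44N2O", "46N2O")
  fits <- d |>
    dplyr::group_by(.data$replicate) |>
    dplyr::group_map(function(grp, key) {
      fs <- purrr::map(targets, function(sp) {
        fit_slope(grp, sp, window = window, value_col = "fit_value")
      })
      names(fs) <- targets
      list(replicate = key$replicate, fits = fs)
    })

  out <- purrr::map_dfr(fits, function(x) {
    tibble(
      replicate = x$replicate,
      v_obs_29n2 = normalize_slope(x$fits[["29N2"]]$slope, biomass, "29N2"),
      v_obs_30n2 = normalize_slope(x$fits[["30N2"]]$slope, biomass, "30N2"),
      v_obs_44n2o = normalize_slope(x$fits[["44N2O"]]$slope, biomass, "44N2O"),
      v_obs_46n2o = normalize_slope(x$fits[["46N2O"]]$slope, biomass, "46N2O"),
      biomass_g = biomass,
      f_label = config$f_label
    )
  })
  structure(out,
    fits = fits,
    class = c("observed_slopes", class(out))
  )
}
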