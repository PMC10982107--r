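#' Total influent nitrogen of the synthetic-medium recipe
#'
#' The feed medium supplies 100 mg N L^-1 each of ammonium and nitrite
#' and no nitrate, so total influent N is 200 mg N L^-1 by default.
#'
#' @param nh4_mg_n_l,no2_mg_n_l,no3_mg_n_l Influent species, mg N L^-1.
#' @return Total influent nitrogen, mg N L^-1.
#' @examples
#' influent_total_n()
#' @export
influent_total_n <- function(nh4_mg_n_l = 100, no2_mg_n_l = 100,
                             no3_mg_n_l = 0) {
  nh4_mg_n_l + no2_mg_n_l + no3_mg_n_l
}

#' N2O conversion ratio over total influent nitrogen
#'
#' Percentage of the influent nitrogen leaving as dissolved N2O, assuming
#' negligible loss of N2O to a gas phase (the reactor runs without a
#' headspace).
#'
#' @param mean_dissolved_n2o Mean effluent dissolved N2O, mg N L^-1.
#' @param influent_n Total influent nitrogen, mg N L^-1 (> 0).
#' @return Conversion ratio in percent.
#' @examples
#' conversion_ratio(0.67, 200) # ~0.34 %
#' @export
conversion_ratio <- function(mean_dissolved_n2o, influent_n) {
  if (any(influent_n <= 0)) {
    abort("`influent_n` must be positive.", class = "n2opair_domain_error")
  }
  100 * mean_dissolved_n2o / influent_n
}

#' Anammox stoichiometric ratio diagnostics
#'
#' Computes the ratios of nitrite consumed and nitrate produced per unit
#' of ammonium consumed from influent-effluent differences, and compares
#' them against reference constants for enriched anammox biomass
#' (defaults 1.32 and 0.26, literature values for the anammox catabolism,
#' configurable). Rows with non-positive ammonium consumption are
#' returned with `NA` ratios and `undefined_flag = TRUE`.
#'
#' @param data A data frame with columns `influent_nh4`, `influent_no2`,
#'   `influent_no3`, `effluent_nh4`, `effluent_no2`, `effluent_no3`
#'   (mg N L^-1), e.g. [simulate_reactor()] output or a period summary.
#' @param ref_no2_nh4,ref_no3_nh4 Reference ratios to compare against.
#'
#' @return The input as a tibble with added columns `dno2_dnh4`,
#'   `dno3_dnh4`, `dev_no2_ratio`, `dev_no3_ratio` (signed deviations
#'   from the references) and `undefined_flag`.
#' @examples
#' stoichiometric_ratios(tibble::tibble(
#'   influent_nh4 = 100, influent_no2 = 100, influent_no3 = 0,
#'   effluent_nh4 = 0, effluent_no2 = 0, effluent_no3 = 26
#' ))
#' @export
stoichiometric_ratios <- function(data, ref_no2_nh4 = 1.32,
                                  ref_no3_nh4 = 0.26) {
  need <- c(
    "influent_nh4", "influent_no2", "influent_no3",
    "effluent_nh4", "effluent_no2", "effluent_no3"
  )
  if (!all(need %in% names(data))) {
    abort(paste0("`data` must have columns: ", paste(need, collapse = ", ")),
      class = "n2opair_parse_error"
    )
  }
  as_tibble(data) |>
    dplyr::mutate(
      d_nh4 = .data$influent_nh4 - .data$effluent_nh4,
      d_no2 = .data$influent_no2 - .data$effluent_no2,
      d_no3_prod = .data$effluent_no3 - .data$influent_no3,
      undefined_flag = .data$d_nh4 <= 0,
      dno2_dnh4 = ifelse(.data$undefined_flag, NA_real_,
        .data$d_no2 / .data$d_nh4
      ),
      dno3_dnh4 = ifelse(.data$undefined_flag, NA_real_,
        .data$d_no3_prod / .data$d_nh4
      ),
      dev_no2_ratio = .data$dno2_dnh4 - ref_no2_nh4,
      dev_no3_ratio = .data$dno3_dnh4 - ref_no3_nh4
    ) |>
    dplyr::select(-dplyr::all_of(c("d_nh4", "d_no2", "d_no3_prod")))
}

#' Period summary of a reactor operation table
#'
#' Means and sample SDs of every measured species over a day window,
#' plus nitrogen removal efficiency
#' `1 - effluent total N / influent total N` and the stoichiometric
#' ratio diagnostics computed on the period means. Dissolved N2O is
#' excluded from the effluent-total-N sum (it is reported separately as a
#' conversion ratio).
#'
#' @param records A [simulate_reactor()]-style table.
#' @param window Length-2 numeric day window, endpoints inclusive;
#'   default spans the whole table.
#'
#' @return A list of class `period_summary`: `window`, `n_days`,
#'   `species` (tibble of mean/sd per column), `removal_efficiency`,
#'   `conversion_ratio_pct` and `ratios` (one-row
#'   [stoichiometric_ratios()] on the period means).
#' @examples
#' period_summary(simulate_reactor(days = 30, seed = 1))
#' @export
period_summary <- function(records, window = NULL) {
  window <- window %||% range(records$day)
  d <- dplyr::filter(records, .data$day >= window[1], .data$day <= window[2])
  if (nrow(d) == 0L) {
    abort("No records inside the requested window.",
      class = "n2opair_domain_error"
    )
  }
  cols <- c(
    "influent_nh4", "influent_no2", "influent_no3",
    "effluent_nh4", "effluent_no2", "effluent_no3",
    "dissolved_n2o", "ph"
  )
  species <- purrr::map_dfr(cols, function(cl) {
    tibble(
      variable = cl,
      mean = mean(d[[cl]]),
      sd = if (nrow(d) >= 2) stats::sd(d[[cl]]) else NA_real_
    )
  })
  mean_of <- function(cl) species$mean[species$variable == cl]
  inf_n <- influent_total_n(
    mean_of("influent_nh4"), mean_of("influent_no2"), mean_of("influent_no3")
  )
  eff_n <- mean_of("effluent_nh4") + mean_of("effluent_no2") +
    mean_of("effluent_no3")
  means_row <- tibble(
    influent_nh4 = mean_of("influent_nh4"),
    influent_no2 = mean_of("influent_no2"),
    influent_no3 = mean_of("influent_no3"),
    effluent_nh4 = mean_of("effluent_nh4"),
    effluent_no2 = mean_of("effluent_no2"),
    effluent_no3 = mean_of("effluent_no3")
  )
  structure(
    list(
      window = window,
      n_days = nrow(d),
      species = species,
      removal_efficiency = 1 - eff_n / inf_n,
      conversion_ratio_pct = conversion_ratio(mean_of("dissolved_n2o"), inf_n),
      ratios = stoichiometric_ratios(means_row)
    ),
    class = "period_summary"
  )
}

#' @export
print.period_summary <- function(x, ...) {
  cat(sprintf(
    "<period_summary> days %g-%g (n = %d)\n", x$window[1], x$window[2],
    x$n_days
  ))
  cat(sprintf("  N removal efficiency:  %.1f%%\n", 100 * x$removal_efficiency))
  cat(sprintf("  N2O conversion ratio:  %.2f%%\n", x$conversion_ratio_pct))
  if (!x$ratios$undefined_flag) {
    cat(sprintf(
      "  dNO2/dNH4 = %.2f, dNO3/dNH4 = %.2f\n",
      x$ratios$dno2_dnh4, x$ratios$dno3_dnh4
    ))
  } else {
    cat("  stoichiometric ratios undefined (no net NH4 consumption)\n")
  }
  invisible(x)
}

#' @export
tidy.period_summary <- function(x, ...) x$species

#' @export
glance.period_summary <- function(x, ...) {
  tibble(
    window_start = x$window[1], window_end = x$window[2], n_days = x$n_days,
    removal_efficiency = x$removal_efficiency,
    conversion_ratio_pct = x$conversion_ratio_pct,
    dno2_dnh4 = x$ratios$dno2_dnh4, dno3_dnh4 = x$ratios$dno3_dnh4
  )
}
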