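#' Write vial time series to delimited text
#'
#' Writes one comma-separated file per replicate
#' (`replicate_<i>.csv`: columns `time_h`, `species`, `headspace_umol`,
#' `dissolved_umol`) plus a `manifest.yaml` recording the vial
#' configuration, simulation parameters and seed, so a simulated data set
#' is fully reconstructible from disk.
#'
#' @param data A [simulate_vial()] result (or any tibble with the same
#'   columns).
#' @param dir Output directory; created if missing.
#' @return Invisibly, the paths written.
#' @export
write_timeseries <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reps <- sort(unique(data$replicate))
  paths <- purrr::map_chr(reps, function(r) {
    path <- file.path(dir, sprintf("replicate_%d.csv", r))
    data |>
      dplyr::filter(.data$replicate == r) |>
      dplyr::select(dplyr::all_of(c(
        "time_h", "species", "headspace_umol", "dissolved_umol"
      ))) |>
      readr::write_csv(path)
    path
  })
  config <- attr(data, "config")
  params <- attr(data, "params")
  manifest <- list(
    files = basename(paths),
    config = if (!is.null(config)) unclass(config),
    params = if (!is.null(params)) {
      p <- unclass(params)
      p$rates <- unclass(p$rates)
      p
    },
    exhausted = isTRUE(attr(data, "exhausted"))
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(c(paths, manifest_path))
}

#' Read a single-replicate vial time series from delimited text
#'
#' Reads the comma-separated dialect written by [write_timeseries()]
#' (header row, UTF-8). Rows are validated — missing columns, unknown
#' species, negative amounts and non-finite times are rejected with the
#' offending row named — and returned sorted by time.
#'
#' @param path CSV file path.
#' @param replicate Replicate id to stamp on the result (default 1).
#' @return A tibble with columns `replicate`, `time_h`, `species`,
#'   `headspace_umol`, `dissolved_umol`, `total_umol`, sorted by time.
#' @export
read_timeseries <- function(path, replicate = 1L) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_h", "species", "headspace_umol", "dissolved_umol")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing column(s) in ", path, ": ",
      paste(missing_cols, collapse = ", ")
    ), class = "n2opair_parse_error")
  }
  bad_species <- which(!d$species %in% SPECIES_ALL)
  if (length(bad_species) > 0) {
    abort(paste0(
      "Unknown species in row ", bad_species[1], ": ",
      d$species[bad_species[1]]
    ), class = "n2opair_parse_error")
  }
  bad_amount <- which(d$headspace_umol < 0 | d$dissolved_umol < 0)
  if (length(bad_amount) > 0) {
    abort(paste0("Negative amount in row ", bad_amount[1], "."),
      class = "n2opair_parse_error"
    )
  }
  bad_time <- which(!is.finite(d$time_h) | d$time_h < 0)
  if (length(bad_time) > 0) {
    abort(paste0("Invalid time in row ", bad_time[1], "."),
      class = "n2opair_parse_error"
    )
  }
  d |>
    dplyr::mutate(
      replicate = as.integer(replicate),
      total_umol = .data$headspace_umol + .data$dissolved_umol
    ) |>
    dplyr::arrange(.data$time_h, match(.data$species, SPECIES_ALL)) |>
    dplyr::select(dplyr::all_of(c(
      "replicate", "time_h", "species",
      "headspace_umol", "dissolved_umol", "total_umol"
    )))
}

#' Read an observed-slopes table from delimited text
#'
#' Columns: `replicate`, `v_obs_29n2`, `v_obs_30n2`, `v_obs_44n2o`,
#' `v_obs_46n2o`, `biomass_g`, `f_label` (mg N g^-1 h^-1; comma-separated,
#' header row).
#'
#' @param path CSV file path.
#' @return A validated tibble ready for [estimate_activities()].
#' @export
read_slopes <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c(
    "replicate", "v_obs_29n2", "v_obs_30n2", "v_obs_44n2o",
    "v_obs_46n2o", "biomass_g", "f_label"
  )
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing column(s) in ", path, ": ",
      paste(missing_cols, collapse = ", ")
    ), class = "n2opair_parse_error")
  }
  if (any(d$biomass_g <= 0)) {
    abort("`biomass_g` must be positive.", class = "n2opair_parse_error")
  }
  purrr::walk(unique(d$f_label), check_label_fraction)
  as_tibble(d)
}

#' Write/read reactor operation tables
#'
#' Plain comma-separated round trip for [simulate_reactor()]-style
#' tables.
#'
#' @param records Operation table.
#' @param path CSV file path.
#' @return `write_operation_table()` returns `path` invisibly;
#'   `read_operation_table()` returns a validated tibble.
#' @name operation-table-io
NULL

#' @rdname operation-table-io
#' @export
write_operation_table <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname operation-table-io
#' @export
read_operation_table <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c(
    "day", "influent_nh4", "influent_no2", "influent_no3",
    "effluent_nh4", "effluent_no2", "effluent_no3", "dissolved_n2o"
  )
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing column(s) in ", path, ": ",
      paste(missing_cols, collapse = ", ")
    ), class = "n2opair_parse_error")
  }
  if (is.unsorted(d$day)) {
    abort("`day` must be non-decreasing.", class = "n2opair_parse_error")
  }
  conc <- setdiff(need, "day")
  bad <- which(purrr::reduce(purrr::map(conc, ~ d[[.x]] < 0), `|`))
  if (length(bad) > 0) {
    abort(paste0("Negative concentration in row ", bad[1], "."),
      class = "n2opair_parse_error"
    )
  }
  as_tibble(d)
}
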