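#' Vial configuration for a sealed 15N tracer incubation
#'
#' Describes the physical assay: a 30-mL serum vial holding 15 mL of
#' anoxic medium (40 mg N L^-1 of 15N-nitrite at label fraction
#' `f_label` and 40 mg N L^-1 of unlabelled ammonium) under 15 mL of
#' headspace, inoculated with ~0.3 g of dewatered biomass and spiked with
#' unlabelled 44N2O, incubated at 30 degC.
#'
#' The biomass-specific rate basis is volatile suspended solids (MLVSS):
#' `mlvss_fraction` converts the wet dewatered pellet mass to its
#' catalytic MLVSS mass (default 0.10, a typical volatile-solids content
#' of dewatered sludge). Both the simulator and the slope normalisation
#' use `biomass_g * mlvss_fraction`, so activity recovery does not depend
#' on the chosen basis; the fraction only controls how fast the finite
#' substrate pools are drawn down.
#'
#' @param v_liquid_ml,v_headspace_ml Liquid and headspace volumes, mL.
#' @param biomass_g Wet dewatered biomass inoculated, g.
#' @param mlvss_fraction MLVSS mass per g of wet pellet, dimensionless.
#' @param temperature_c Incubation temperature, degC.
#' @param f_label 15N fraction of the nitrite pool, see
#'   [pairing_probabilities()].
#' @param no2_mg_n_l,nh4_mg_n_l Initial nitrite and ammonium, mg N L^-1.
#' @param n2o_added_umol Unlabelled 44N2O spike, umol of molecules.
#'
#' @return A list of class `vial_config`.
#' @examples
#' vial_config()
#' @export
vial_config <- function(v_liquid_ml = 15,
                        v_headspace_ml = 15,
                        biomass_g = 0.3,
                        mlvss_fraction = 0.1,
                        temperature_c = 30,
                        f_label = 0.98,
                        no2_mg_n_l = 40,
                        nh4_mg_n_l = 40,
                        n2o_added_umol = 5) {
  check_label_fraction(f_label)
  if (v_liquid_ml <= 0 || v_headspace_ml <= 0 || biomass_g <= 0 ||
    mlvss_fraction <= 0 || mlvss_fraction > 1) {
    abort("Volumes, biomass and mlvss_fraction must be positive (fraction <= 1).",
      class = "n2opair_domain_error"
    )
  }
  if (no2_mg_n_l < 0 || nh4_mg_n_l < 0 || n2o_added_umol < 0) {
    abort("Initial substrate amounts must be non-negative.",
      class = "n2opair_domain_error"
    )
  }
  structure(
    list(
      v_liquid_ml = v_liquid_ml, v_headspace_ml = v_headspace_ml,
      biomass_g = biomass_g, mlvss_fraction = mlvss_fraction,
      temperature_c = temperature_c, f_label = f_label,
      no2_mg_n_l = no2_mg_n_l, nh4_mg_n_l = nh4_mg_n_l,
      n2o_added_umol = n2o_added_umol
    ),
    class = "vial_config"
  )
}

#' Catalytic (MLVSS) biomass of a vial, grams
#' @param config A [vial_config()].
#' @return Scalar grams of MLVSS used for rate scaling and normalisation.
#' @export
biomass_mlvss_g <- function(config) {
  config$biomass_g * config$mlvss_fraction
}

#' Simulation parameters for the vial generator
#'
#' @param rates True process rates, a [process_rates()]; the default is
#'   the operating point reported for an N2O-fed anammox biomass
#'   (anammox 0.9, N2O production 0.037, N2O consumption 0.02 + 0.19
#'   mg N g^-1 h^-1).
#' @param kinetic_order `"zero"` (default; constant rates while substrate
#'   lasts, matching the linear-slope analysis) or `"first"`
#'   (consumption terms proportional to the instantaneous N2O pool,
#'   scaled to match the nominal rate at the initial pool size).
#' @param consumption_allocation `"source"` (default; nitrite-derived N2O
#'   is consumed in the binomial proportions it is produced in, the
#'   assumption under which the inversion is exact) or `"pool"`
#'   (consumption removes isotopologues in proportion to the
#'   instantaneous pool composition).
#' @param sampling_times Headspace sampling times, hours; strictly
#'   increasing with at least two points inside the 4-15 h slope window.
#' @param noise_cv Relative SD of multiplicative Gaussian measurement
#'   noise applied to reported headspace amounts (negative noise factors
#'   are censored at zero). 0 disables noise.
#' @param n_replicates Number of replicate vials (noise realisations).
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   output.
#' @param dt Euler step, hours (must be <= 0.01).
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(rates = process_rates(
                         anammox = 0.9, n2o_production = 0.037,
                         n2o_consumption_nitrite = 0.02,
                         n2o_consumption_exo = 0.19
                       ),
                       kinetic_order = c("zero", "first"),
                       consumption_allocation = c("source", "pool"),
                       sampling_times = c(0, 2, 4, 6, 9, 12, 15),
                       noise_cv = 0.02,
                       n_replicates = 3,
                       seed = 101L,
                       dt = 0.01) {
  kinetic_order <- match.arg(kinetic_order)
  consumption_allocation <- match.arg(consumption_allocation)
  if (any(diff(sampling_times) <= 0)) {
    abort("`sampling_times` must be strictly increasing.",
      class = "n2opair_domain_error"
    )
  }
  if (sum(sampling_times >= 4 & sampling_times <= 15) < 2) {
    abort("Need at least two sampling times inside [4, 15] h.",
      class = "n2opair_domain_error"
    )
  }
  if (noise_cv < 0) {
    abort("`noise_cv` must be >= 0.", class = "n2opair_domain_error")
  }
  if (dt <= 0 || dt > 0.01) {
    abort("`dt` must be in (0, 0.01].", class = "n2opair_domain_error")
  }
  structure(
    list(
      rates = rates, kinetic_order = kinetic_order,
      consumption_allocation = consumption_allocation,
      sampling_times = sampling_times, noise_cv = noise_cv,
      n_replicates = as.integer(n_replicates), seed = as.integer(seed),
      dt = dt
    ),
    class = "sim_params"
  )
}

# run a block of code with the global RNG stream isolated to `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate replicate vial incubations
#'
#' Integrates the sealed-vial mass balance with Euler steps: anammox pairs
#' one nitrite N (15N with probability `f_label`) with one unlabelled
#' ammonium N into N2; denitrification converts pairs of nitrite N into
#' N2O split binomially across 44/45/46; N2O consumption reduces
#' nitrite-derived and exogenous N2O to the corresponding N2
#' isotopologues. Rates taper to zero when a substrate pool empties (the
#' result carries an `exhausted` attribute and a warning is emitted).
#' Every gas amount is split between headspace and liquid at instantaneous
#' Henry equilibrium; multiplicative measurement noise is applied to the
#' reported headspace amounts only.
#'
#' @param config A [vial_config()].
#' @param params A [sim_params()].
#'
#' @return A tibble of class `vial_sim` with columns `replicate`,
#'   `time_h`, `species`, `headspace_umol`, `dissolved_umol`,
#'   `total_umol`. Attributes: `config`, `params`, `truth` (the true
#'   rates), `substrates` (noise-free substrate trajectories, umol N) and
#'   `exhausted`.
#' @examples
#' sim <- simulate_vial(vial_config(), sim_params(noise_cv = 0, seed = 1))
#' head(sim)
#' @export
simulate_vial <- function(config = vial_config(), params = sim_params()) {
  stopifnot(inherits(config, "vial_config"), inherits(params, "sim_params"))
  traj <- integrate_vial(config, params)

  fh <- c(
    N2 = partition_fractions(
      "N2", config$temperature_c,
      config$v_headspace_ml, config$v_liquid_ml
    )$headspace,
    N2O = partition_fractions(
      "N2O", config$temperature_c,
      config$v_headspace_ml, config$v_liquid_ml
    )$headspace
  )

  base <- traj$gases |>
    dplyr::mutate(
      frac_head = unname(fh[parent_gas(.data$species)]),
      headspace_true = .data$total_umol * .data$frac_head,
      dissolved_umol = .data$total_umol * (1 - .data$frac_head)
    )

  out <- with_local_seed(params$seed, {
    purrr::map_dfr(seq_len(params$n_replicates), function(rep) {
      noise <- if (params$noise_cv > 0) {
        pmax(stats::rnorm(nrow(base), mean = 1, sd = params$noise_cv), 0)
      } else {
        rep(1, nrow(base))
      }
      dplyr::mutate(base,
        replicate = rep,
        headspace_umol = .data$headspace_true * noise
      )
    })
  })

  out <- out |>
    dplyr::transmute(
      replicate = .data$replicate,
      time_h = .data$time_h,
      species = .data$species,
      headspace_umol = .data$headspace_umol,
      dissolved_umol = .data$dissolved_umol,
      total_umol = .data$headspace_umol + .data$dissolved_umol
    )

  if (traj$exhausted) {
    warn("A substrate pool was exhausted before the final sampling time; rates tapered to zero.",
      class = "n2opair_exhaustion_warning"
    )
  }
  structure(
    out,
    config = config, params = params, truth = params$rates,
    substrates = traj$substrates, exhausted = traj$exhausted,
    class = c("vial_sim", class(out))
  )
}

# deterministic (noise-free) trajectory of total vial amounts
integrate_vial <- function(config, params) {
  f <- config$f_label
  pp <- pairing_probabilities(f)
  ph <- pp$p_heavy
  pm <- pp$p_mixed
  pl <- pp$p_light
  m <- biomass_mlvss_g(config)

  # molecular production rates, umol of molecules per hour
  a0 <- params$rates$anammox * m / MG_N_PER_UMOL_PAIR
  p0 <- params$rates$n2o_production * m / MG_N_PER_UMOL_PAIR
  cn0 <- params$rates$n2o_consumption_nitrite * m / MG_N_PER_UMOL_PAIR
  cx0 <- params$rates$n2o_consumption_exo * m / MG_N_PER_UMOL_PAIR

  # substrate pools, umol N
  no2_tot <- config$no2_mg_n_l * config$v_liquid_ml / 1000 / (MG_N_PER_MMOL_N / 1000)
  nh4 <- config$nh4_mg_n_l * config$v_liquid_ml / 1000 / (MG_N_PER_MMOL_N / 1000)
  n15 <- f * no2_tot
  n14 <- (1 - f) * no2_tot

  # gas pools, umol of molecules; exogenous and nitrite-derived 44N2O
  # are tracked separately so source-proportional consumption is exact
  g <- c(
    g28 = 0, g29 = 0, g30 = 0,
    g44_exo = config$n2o_added_umol, g44_den = 0, g45 = 0, g46 = 0
  )
  pool0 <- config$n2o_added_umol

  t_max <- max(params$sampling_times)
  grid <- sort(unique(c(seq(0, t_max, by = params$dt), params$sampling_times)))
  sample_set <- params$sampling_times
  exhausted <- FALSE

  n_s <- length(sample_set)
  rec <- matrix(0, nrow = n_s, ncol = 6,
    dimnames = list(NULL, SPECIES_ALL)
  )
  sub_rec <- matrix(0, nrow = n_s, ncol = 3,
    dimnames = list(NULL, c("no2_15_umol_n", "no2_14_umol_n", "nh4_umol_n"))
  )
  record <- function(i) {
    rec[i, ] <<- c(
      g[["g28"]], g[["g29"]], g[["g30"]],
      g[["g44_exo"]] + g[["g44_den"]], g[["g45"]], g[["g46"]]
    )
    sub_rec[i, ] <<- c(n15, n14, nh4)
  }
  next_sample <- 1L
  if (sample_set[1] == 0) {
    record(1L)
    next_sample <- 2L
  }

  first_order <- params$kinetic_order == "first"
  pool_mode <- params$consumption_allocation == "pool"

  for (k in seq_len(length(grid) - 1L)) {
    dt <- grid[k + 1L] - grid[k]

    # nominal rates this step
    a <- a0
    p <- p0
    if (first_order) {
      pool_now <- g[["g44_exo"]] + g[["g44_den"]] + g[["g45"]] + g[["g46"]]
      scale_fo <- if (pool0 > 0) pool_now / pool0 else 0
      cn <- cn0 * scale_fo
      cx <- cx0 * scale_fo
    } else {
      cn <- cn0
      cx <- cx0
    }

    # substrate limitation: shared nitrite pool, private ammonium pool
    need_no2 <- (a + 2 * p) * dt
    s_no2 <- if (need_no2 > 0) min(1, (n15 + n14) / need_no2) else 1
    need_nh4 <- a * dt
    s_nh4 <- if (need_nh4 > 0) min(1, nh4 / need_nh4) else 1
    a_eff <- a * min(s_no2, s_nh4)
    p_eff <- p * s_no2
    if (s_no2 < 1 || s_nh4 < 1) exhausted <- TRUE

    # production half-step (operator splitting; exact for zero-order
    # kinetics because all trajectories are piecewise linear)
    g[["g46"]] <- g[["g46"]] + dt * p_eff * ph
    g[["g45"]] <- g[["g45"]] + dt * p_eff * pm
    g[["g44_den"]] <- g[["g44_den"]] + dt * p_eff * pl
    g[["g29"]] <- g[["g29"]] + dt * a_eff * f
    g[["g28"]] <- g[["g28"]] + dt * a_eff * (1 - f)
    n15 <- n15 - dt * (a_eff * f + 2 * p_eff * f)
    n14 <- n14 - dt * (a_eff * (1 - f) + 2 * p_eff * (1 - f))
    nh4 <- nh4 - dt * a_eff

    # consumption half-step, limited by the post-production pools
    lim <- function(pool, draw) if (draw > 0) pool / draw else Inf
    if (pool_mode) {
      pool <- g[["g44_exo"]] + g[["g44_den"]] + g[["g45"]] + g[["g46"]]
      ct <- cn + cx
      s_c <- min(1, lim(pool, ct * dt))
      rm_tot <- ct * s_c * dt
      if (rm_tot > 0 && pool > 0) {
        w <- c(g[["g44_exo"]], g[["g44_den"]], g[["g45"]], g[["g46"]]) / pool
        rm_amt <- rm_tot * w
        g[["g44_exo"]] <- g[["g44_exo"]] - rm_amt[1]
        g[["g44_den"]] <- g[["g44_den"]] - rm_amt[2]
        g[["g45"]] <- g[["g45"]] - rm_amt[3]
        g[["g46"]] <- g[["g46"]] - rm_amt[4]
        g[["g28"]] <- g[["g28"]] + rm_amt[1] + rm_amt[2]
        g[["g29"]] <- g[["g29"]] + rm_amt[3]
        g[["g30"]] <- g[["g30"]] + rm_amt[4]
      }
      if (s_c < 1) exhausted <- TRUE
    } else {
      # source-proportional: remove from the nitrite-derived pools at the
      # binomial composition, and from the exogenous pool separately
      s_cn <- min(
        1,
        lim(g[["g46"]], cn * ph * dt),
        lim(g[["g45"]], cn * pm * dt),
        lim(g[["g44_den"]], cn * pl * dt)
      )
      s_cx <- min(1, lim(g[["g44_exo"]], cx * dt))
      cn_eff <- cn * s_cn
      cx_eff <- cx * s_cx
      if (s_cn < 1 || s_cx < 1) exhausted <- TRUE
      g[["g46"]] <- g[["g46"]] - dt * cn_eff * ph
      g[["g45"]] <- g[["g45"]] - dt * cn_eff * pm
      g[["g44_den"]] <- g[["g44_den"]] - dt * cn_eff * pl
      g[["g44_exo"]] <- g[["g44_exo"]] - dt * cx_eff
      g[["g30"]] <- g[["g30"]] + dt * cn_eff * ph
      g[["g29"]] <- g[["g29"]] + dt * cn_eff * pm
      g[["g28"]] <- g[["g28"]] + dt * (cn_eff * pl + cx_eff)
    }

    # guard float dust at pool boundaries
    g[g < 0 & g > -1e-9] <- 0
    if (n15 < 0 && n15 > -1e-9) n15 <- 0
    if (n14 < 0 && n14 > -1e-9) n14 <- 0
    if (nh4 < 0 && nh4 > -1e-9) nh4 <- 0

    t_now <- grid[k + 1L]
    if (next_sample <= n_s && isTRUE(all.equal(t_now, sample_set[next_sample]))) {
      record(next_sample)
      next_sample <- next_sample + 1L
    }
  }

  gases <- tibble(
    time_h = rep(sample_set, each = 6L),
    species = rep(SPECIES_ALL, times = n_s),
    total_umol = as.numeric(t(rec))
  )
  substrates <- dplyr::bind_cols(time_h = sample_set, as_tibble(sub_rec))
  list(gases = gases, substrates = substrates, exhausted = exhausted)
}

#' Simulate a reactor operation table
#'
#' Draws per-day influent/effluent nitrogen species, dissolved N2O and pH
#' as independent Gaussians around the supplied means; negative draws are
#' censored to zero (concentrations cannot be negative). SD = 0 yields
#' constant columns. Defaults emulate the late operating period of an
#' anammox membrane-biofilm reactor without external N2O supply:
#' 100 + 100 mg N L^-1 influent ammonium + nitrite, effluent residuals of
#' ~14 and ~18 mg N L^-1, nitrate production near the anammox
#' stoichiometry, and 0.67 mg N L^-1 dissolved N2O.
#'
#' @param days Number of daily records.
#' @param means,sds Named numeric vectors with entries `influent_nh4`,
#'   `influent_no2`, `influent_no3`, `effluent_nh4`, `effluent_no2`,
#'   `effluent_no3`, `dissolved_n2o`, `ph` (mg N L^-1 except pH).
#' @param hrt_d Hydraulic retention time, days.
#' @param seed Integer RNG seed.
#'
#' @return A tibble with one row per day: `day`, the eight measured
#'   columns, and `hrt_d`.
#' @examples
#' simulate_reactor(days = 5, seed = 7)
#' @export
simulate_reactor <- function(days,
                             means = c(
                               influent_nh4 = 100, influent_no2 = 100,
                               influent_no3 = 0,
                               effluent_nh4 = 13.8, effluent_no2 = 18.3,
                               effluent_no3 = 22.4,
                               dissolved_n2o = 0.67, ph = 8.13
                             ),
                             sds = c(
                               influent_nh4 = 2, influent_no2 = 2,
                               influent_no3 = 0,
                               effluent_nh4 = 4, effluent_no2 = 4,
                               effluent_no3 = 3,
                               dissolved_n2o = 0.38, ph = 0.30
                             ),
                             hrt_d = 1,
                             seed = 101L) {
  cols <- c(
    "influent_nh4", "influent_no2", "influent_no3",
    "effluent_nh4", "effluent_no2", "effluent_no3",
    "dissolved_n2o", "ph"
  )
  if (!all(cols %in% names(means)) || !all(cols %in% names(sds))) {
    abort(paste0(
      "`means` and `sds` must be named vectors with entries: ",
      paste(cols, collapse = ", ")
    ), class = "n2opair_domain_error")
  }
  if (any(sds[cols] < 0)) {
    abort("`sds` must be non-negative.", class = "n2opair_domain_error")
  }
  with_local_seed(seed, {
    draws <- purrr::map(cols, function(cl) {
      pmax(stats::rnorm(days, mean = means[[cl]], sd = sds[[cl]]), 0)
    })
    names(draws) <- cols
    dplyr::bind_cols(day = seq_len(days), as_tibble(draws), hrt_d = hrt_d)
  })
}
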