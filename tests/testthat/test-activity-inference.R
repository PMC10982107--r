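test_that("production equation reproduces worked examples", {
  expect_equal(n2o_production_activity(0.01, 0.04, f = 1), 0.05, tolerance = 1e-12)
  expect_equal(
    n2o_production_activity(0.0192, 0.0288, f = 0.98),
    0.048 / 0.9604,
    tolerance = 1e-12
  )
  # exact inversion of the forward model for any nitrite-derived consumption
  r <- forward_species_rates(
    process_rates(n2o_production = 0.037, n2o_consumption_nitrite = 0.015),
    f = 0.98
  )
  v <- setNames(r$rate_mg_n_g_h, r$species)
  expect_equal(
    n2o_production_activity(v[["30N2"]], v[["46N2O"]], f = 0.98),
    0.037,
    tolerance = 1e-12
  )
})

test_that("consumption equation reproduces worked examples and its known bias", {
  expect_equal(n2o_consumption_activity(0, -0.1, f = 0.5), 0.1, tolerance = 1e-12)
  expect_equal(
    n2o_consumption_activity(0.019208, -0.19, f = 0.98),
    0.21,
    tolerance = 1e-12
  )
  # forward model with P = 0: the printed equation overestimates by
  # (1-F)^2 * C_nitrite; the 46N2O correction removes the bias exactly
  r <- forward_species_rates(
    process_rates(n2o_consumption_nitrite = 0.02, n2o_consumption_exo = 0.19),
    f = 0.98
  )
  v <- setNames(r$rate_mg_n_g_h, r$species)
  expect_equal(
    n2o_consumption_activity(v[["30N2"]], v[["44N2O"]], f = 0.98),
    0.21 + (1 - 0.98)^2 * 0.02,
    tolerance = 1e-9
  )
  expect_equal(
    n2o_consumption_activity(v[["30N2"]], v[["44N2O"]],
      f = 0.98,
      v_obs_46n2o = v[["46N2O"]]
    ),
    0.21,
    tolerance = 1e-12
  )
})

test_that("anammox equation reproduces worked examples", {
  expect_equal(anammox_activity(0.7, 0.1, f = 1), 0.7, tolerance = 1e-12)
  expect_equal(
    anammox_activity(0.980784, 0.019208, f = 0.98), 1.0,
    tolerance = 1e-12
  )
})

test_that("anammox inversion is exact against the forward model", {
  withr::with_seed(41, {
    for (i in seq_len(1000)) {
      a <- runif(1, 0, 2)
      cn <- runif(1, 0, 0.5)
      f <- runif(1, 0.5, 1)
      r <- forward_species_rates(
        process_rates(anammox = a, n2o_consumption_nitrite = cn),
        f = f
      )
      v <- setNames(r$rate_mg_n_g_h, r$species)
      expect_equal(anammox_activity(v[["29N2"]], v[["30N2"]], f), a,
        tolerance = max(1e-9 * a, 1e-12)
      )
    }
  })
})

test_that("label-fraction limits and monotonicity behave as expected", {
  # F -> 1: equations reduce to plain bookkeeping
  expect_equal(n2o_production_activity(0.01, 0.04, 1), 0.01 + 0.04)
  expect_equal(n2o_consumption_activity(0.01, -0.2, 1), 0.01 + 0.2)
  expect_equal(anammox_activity(0.9, 0.5, 1), 0.9)
  # production strictly increasing in both slopes, consumption strictly
  # decreasing in the (signed) 44N2O slope
  expect_gt(
    n2o_production_activity(0.02, 0.03),
    n2o_production_activity(0.01, 0.03)
  )
  expect_gt(
    n2o_production_activity(0.01, 0.04),
    n2o_production_activity(0.01, 0.03)
  )
  expect_gt(
    n2o_consumption_activity(0.01, -0.3),
    n2o_consumption_activity(0.01, -0.2)
  )
})

test_that("replicate aggregation computes mean and sample SD", {
  agg <- aggregate_replicates(tibble::tibble(
    anammox = c(1, 1, 1),
    n2o_production = c(0.7, 0.9, 1.1),
    n2o_consumption = c(0.2, 0.2, 0.2)
  ))
  expect_equal(agg$mean[agg$activity == "anammox"], 1)
  expect_equal(agg$sd[agg$activity == "anammox"], 0)
  expect_equal(agg$mean[agg$activity == "n2o_production"], 0.9, tolerance = 1e-12)
  expect_equal(agg$sd[agg$activity == "n2o_production"], 0.2, tolerance = 1e-12)
  # single replicate: mean passes through, SD undefined
  one <- aggregate_replicates(tibble::tibble(
    anammox = 0.5, n2o_production = 0.1, n2o_consumption = 0.2
  ))
  expect_equal(one$mean[one$activity == "anammox"], 0.5)
  expect_true(is.na(one$sd[one$activity == "anammox"]))
  expect_error(
    aggregate_replicates(tibble::tibble(
      anammox = numeric(), n2o_production = numeric(),
      n2o_consumption = numeric()
    )),
    class = "n2opair_domain_error"
  )
})

test_that("estimate_activities applies the equations per replicate", {
  # slopes generated by the forward model at A = 1, Cn = 0.02, Cx = 0.19,
  # P = 0 (so the nitrite-derived 44N2O term is -Cn (1-F)^2)
  slopes <- tibble::tibble(
    replicate = 1:2,
    v_obs_29n2 = c(0.980784, 0.980784),
    v_obs_30n2 = c(0.019208, 0.019208),
    v_obs_44n2o = c(-0.190008, -0.190008),
    v_obs_46n2o = c(-0.019208, -0.019208),
    biomass_g = 0.03,
    f_label = 0.98
  )
  acts <- estimate_activities(slopes, correct_44n2o_bias = FALSE)
  expect_equal(acts$anammox, c(1, 1), tolerance = 1e-9)
  expect_equal(acts$n2o_consumption, rep(0.21 + 0.0004 * 0.02, 2),
    tolerance = 1e-9
  )
  acts2 <- estimate_activities(slopes)
  expect_equal(acts2$n2o_consumption, c(0.21, 0.21), tolerance = 1e-9)
  # negative estimates are reported, not clamped, and flagged
  slopes$v_obs_29n2 <- c(-0.1, 0.9)
  acts3 <- estimate_activities(slopes)
  expect_lt(acts3$anammox[1], 0)
  expect_true(acts3$negative_flag[1])
  expect_false(acts3$negative_flag[2])
})

test_that("Welch test matches the textbook two-sample computation", {
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- welch_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p_value, 0.01)
  # hand Welch-Satterthwaite on unequal variances
  x <- c(0.7, 0.9, 1.1)
  y <- c(1.4, 1.5, 1.9)
  out <- welch_test(x, y)
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$df, df_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
})

test_that("degenerate Welch inputs follow the stated conventions", {
  eq <- welch_test(c(1, 1, 1), c(1, 1, 1))
  expect_true(eq$degenerate)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$t_statistic, 0)
  ne <- welch_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(ne$degenerate)
  expect_equal(ne$p_value, 0)
  expect_error(welch_test(1, c(1, 2)), class = "n2opair_domain_error")
})

test_that("compare_groups reports all three activities", {
  withr::with_seed(5, {
    a <- tibble::tibble(
      anammox = rnorm(3, 0.9, 0.1),
      n2o_production = rnorm(3, 0.037, 0.005),
      n2o_consumption = rnorm(3, 0.21, 0.02)
    )
    b <- tibble::tibble(
      anammox = rnorm(3, 0.97, 0.1),
      n2o_production = rnorm(3, 0.039, 0.005),
      n2o_consumption = rnorm(3, 0.14, 0.02)
    )
  })
  cmp <- compare_groups(a, b)
  expect_equal(cmp$activity, c("anammox", "n2o_production", "n2o_consumption"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$df > 0))
})
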