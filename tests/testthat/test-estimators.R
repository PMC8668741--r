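test_that("BACI interaction is the ratio of ratios and ignores main effects", {
  searches <- cell_searches(list(impact_before = 10, impact_after = 5,
                                 control_before = 10, control_after = 10))
  est <- fit_baci(searches)
  expect_equal(est$reduction_pct, 50, tolerance = 0.01)
  expect_true(est$ci_low_pct <= est$reduction_pct &&
                est$reduction_pct <= est$ci_high_pct)

  # site and period main effects are subtracted out of the interaction
  shifted <- cell_searches(list(impact_before = 10 * 3, impact_after = 5 * 3 * 2,
                                control_before = 10, control_after = 10 * 2))
  expect_equal(fit_baci(shifted)$reduction_pct, 50, tolerance = 0.01)

  missing_cell <- dplyr::filter(searches,
                                !(site == "control" & period == "after"))
  expect_error(fit_baci(missing_cell), "control-after")
})

test_that("BACI on geese-study cell totals gives the crude ratio-of-ratios reduction", {
  # cell totals 164.01 / 51.49 / 69.67 / 36.34 spread over equal replicates;
  # crude ratio of ratios (51.49/164.01)/(36.34/69.67) = 0.602 -> 39.8%
  searches <- cell_searches(list(impact_before = 164.01 / 20,
                                 impact_after = 51.49 / 20,
                                 control_before = 69.67 / 20,
                                 control_after = 36.34 / 20))
  crude <- 100 * (1 - (51.49 / 164.01) / (36.34 / 69.67))
  est <- fit_baci(searches)
  expect_equal(est$reduction_pct, crude, tolerance = 0.01)
  expect_equal(crude, 39.8, tolerance = 0.002)
})

test_that("BA estimates the raw period rate ratio at the impact site", {
  halved <- cell_searches(list(impact_before = 8, impact_after = 4,
                               control_before = 1, control_after = 1))
  expect_equal(fit_ba(halved)$reduction_pct, 50, tolerance = 0.01)

  flat <- cell_searches(list(impact_before = 6, impact_after = 6,
                             control_before = 1, control_after = 1))
  est <- fit_ba(flat)
  expect_equal(est$reduction_pct, 0, tolerance = 0.01)
  expect_equal(est$p_value, 1, tolerance = 1e-6)

  expect_error(fit_ba(dplyr::filter(halved, period == "before")),
               "both periods")
})

test_that("BA is fooled by a flight-intensity doubling that BACI-style data encode", {
  # omega = 2 doubles flights in both sites; with no diverter effect the BA
  # period contrast reports a spurious doubling (-100% "reduction")
  set.seed(21)
  r <- run_comparison("base", n_sims = 40, methods = "BA",
                      omega = 2, gamma = 1, lambda = 0, seed = 21)
  expect_lt(mean(r$reduction_est_pct), -60)
})

test_that("NB fusion reduces to BA when exposure is flat", {
  set.seed(22)
  y <- rnbinom(40, size = 2, mu = rep(c(8, 4), each = 20))
  period <- rep(c("before", "after"), each = 20)
  searches <- tibble::tibble(site = "impact", period = period, n_carcass = y,
                             interval_days = 1L)
  obs <- make_fusion(period, y, exposure_A = rep(500, 40))
  ba <- fit_ba(searches)
  fu <- fit_nb_fusion(obs)
  expect_equal(fu$coefficient, ba$coefficient, tolerance = 1e-6)
})

test_that("doubled exposure with unchanged carcasses is a halved collision rate", {
  set.seed(23)
  y <- rnbinom(60, size = 5, mu = 6)
  obs <- make_fusion(rep(c("before", "after"), each = 30), rep(y, 2)[1:60],
                     exposure_A = rep(c(1e5, 2e5), each = 30))
  obs$n_carcass <- c(y[1:30], y[1:30])  # identical carcass counts per period
  est <- fit_nb_fusion(obs)
  expect_equal(est$reduction_pct, 50, tolerance = 0.5)

  allzero <- make_fusion(rep(c("before", "after"), each = 5), rep(1, 10),
                         exposure_A = rep(0, 10))
  expect_error(fit_nb_fusion(allzero), "zero")
})

test_that("binomial fusion agrees with NB fusion and drops degenerate rows", {
  set.seed(24)
  A <- rnbinom(80, size = 0.41, mu = 1254)
  lam <- rep(c(1, 0.5), each = 40)
  y <- rbinom(80, A, 0.001 * lam)
  obs <- make_fusion(rep(c("before", "after"), each = 40), y, exposure_A = A)
  nb <- fit_nb_fusion(obs)
  b <- suppressWarnings(fit_b_fusion(obs, c = 1))  # a few zero-flight rows
  expect_equal(b$reduction_pct, nb$reduction_pct, tolerance = 3)

  # c = 1 on small fractional rates degrades some rows to (0, 0): dropped
  frac <- make_fusion(rep(c("before", "after"), each = 10),
                      rep(c(2, 0.3), 10), exposure_A = rep(c(4, 0.2), 10))
  expect_warning(fit_b_fusion(frac, c = 1), "dropped")
})

test_that("default binomial fusion scaling follows the recommended constant", {
  expect_equal(formals(fit_b_fusion)$c, 10000)
})

test_that("synchronicity test recovers the flight-rate ratio of ratios", {
  rates <- list(impact_before = 10, impact_after = 20,
                control_before = 10, control_after = 10)
  flights <- cell_searches(rates, reps = 25) |>
    dplyr::rename(individuals = n_carcass) |>
    dplyr::mutate(individuals = as.integer(individuals), hours = 1)
  res <- test_synchronicity(flights)
  expect_equal(res$interaction_coefficient, log(2), tolerance = 1e-4)
  expect_equal(res$expected_baci_bias_pct, 100, tolerance = 0.1)

  sync <- cell_searches(list(impact_before = 12, impact_after = 12,
                             control_before = 12, control_after = 12),
                        reps = 25) |>
    dplyr::rename(individuals = n_carcass) |>
    dplyr::mutate(individuals = as.integer(individuals), hours = 1)
  res0 <- test_synchronicity(sync)
  expect_equal(res0$expected_baci_bias_pct, 0, tolerance = 0.1)
  expect_equal(res0$p_value, 1, tolerance = 1e-6)
})

test_that("simulated synchronicity violation of 1.74 is estimated without bias", {
  set.seed(25)
  coefs <- replicate(40, {
    p <- sim_params(gamma = 1.74, n_obs_per_cell = 200)
    cells <- expand.grid(period = c("before", "after"),
                         site = c("impact", "control"),
                         stringsAsFactors = FALSE)
    fl <- dplyr::bind_rows(purrr::pmap(cells, function(period, site) {
      tibble::tibble(site = site, period = period,
                     individuals = rnbinom(200, size = p$theta1,
                                           mu = cell_flight_mean(site, period, p)),
                     hours = 1)
    }))
    test_synchronicity(fl)$interaction_coefficient
  })
  expect_equal(mean(coefs), log(1.74), tolerance = 0.12)
  # on the percent scale the estimated BACI bias sits near +74%
  expect_equal(mean(100 * (exp(coefs) - 1)), 74, tolerance = 12)
})

test_that("reduction scale maps coefficients as 100*(1 - exp(beta))", {
  expect_equal(reduction_from_coefficient(0), 0)
  expect_equal(reduction_from_coefficient(log(0.5)), 50)
  expect_equal(reduction_from_coefficient(log(1 - 0.892)), 89.2)
})

test_that("tidy and glance expose the fit in broom style", {
  searches <- cell_searches(list(impact_before = 10, impact_after = 5,
                                 control_before = 10, control_after = 10))
  est <- fit_baci(searches)
  td <- tidy(est)
  expect_setequal(td$term, names(est$fit$coefficients))
  gl <- glance(est)
  expect_equal(gl$method, "BACI")
  expect_equal(gl$reduction_pct, est$reduction_pct)
  expect_s3_class(autoplot(est), "ggplot")
})
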