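#' Simulation parameters for paired flight/carcass datasets
#'
#' Bundles and validates the parameter vector of the two-stage Monte Carlo
#' model used throughout the simulation study. The defaults are calibrated
#' to the geese data of the motivating field study: pooled flight counts per
#' search interval are negative binomial with mean `mu1 = 1254` and
#' dispersion `theta1 = 0.41` (variance mu + mu^2/theta), and each observed
#' crossing collides independently with probability `zeta = 0.001`.
#'
#' @param mu1 Mean pooled flight count per search interval (before period).
#' @param theta1 Negative binomial dispersion of flight counts.
#' @param zeta Per-bird collision probability, expressed per *observed*
#'   crossing.
#' @param omega Multiplicative change in flight intensity from the before to
#'   the after period, at both sites (>= 1).
#' @param gamma Synchronicity-violation factor: an extra flight-intensity
#'   multiplier applied to the impact site in the after period only (>= 1).
#'   `gamma > 1` inflates impact-after carcass numbers and thereby biases
#'   BA and BACI estimates, counteracting a true diverter effect.
#' @param lambda Diverter-induced reduction of the collision probability at
#'   the impact site in the after period, in `[0, 1)`; the collision
#'   probability there is `zeta * (1 - lambda)`.
#' @param n_obs_per_cell Number of search intervals simulated per site x
#'   period cell (default 60, matching the density of the motivating
#'   study's data).
#' @param detect_prob Fraction of crossing birds that is observed; the
#'   observed flight count fed to the fusion models is a binomial thinning
#'   of the true count, drawn independently of the collision events.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(mu1 = 1254, theta1 = 0.41, zeta = 0.001,
                       omega = 1, gamma = 1, lambda = 0,
                       n_obs_per_cell = 60L, detect_prob = 1) {
  stopifnot(mu1 > 0, theta1 > 0,
            zeta >= 0, zeta <= 1,
            omega >= 1, gamma >= 1,
            lambda >= 0, lambda < 1,
            n_obs_per_cell >= 1,
            detect_prob > 0, detect_prob <= 1)
  structure(list(mu1 = mu1, theta1 = theta1, zeta = zeta, omega = omega,
                 gamma = gamma, lambda = lambda,
                 n_obs_per_cell = as.integer(n_obs_per_cell),
                 detect_prob = detect_prob),
            class = "sim_params")
}

#' Robustness-scenario presets
#'
#' Applies one of the simulation-study scenario transformations to a
#' parameter set: `low_intensity` divides the flight mean by 100 and
#' multiplies the collision probability by 100 (same expected carcass
#' numbers from far fewer crossings); `high_variance` lowers the dispersion
#' to `theta1 = 0.2` (stronger overdispersion); `partial_detection` sets
#' `detect_prob = 0.01` so only 1% of crossing birds are observed.
#'
#' @param scenario One of `"base"`, `"low_intensity"`, `"high_variance"`,
#'   `"partial_detection"`.
#' @param params A `sim_params` object to transform.
#' @return The transformed `sim_params`.
#' @export
scenario_params <- function(scenario = c("base", "low_intensity",
                                         "high_variance", "partial_detection"),
                            params = sim_params()) {
  scenario <- match.arg(scenario)
  switch(scenario,
    base = params,
    low_intensity = {
      params$mu1 <- params$mu1 / 100
      params$zeta <- min(1, params$zeta * 100)
      params
    },
    high_variance = { params$theta1 <- 0.2; params },
    partial_detection = { params$detect_prob <- 0.01; params }
  )
}

#' Expected flight count of one site x period cell
#'
#' Before period (both sites): `mu1`. Control site, after period:
#' `mu1 * omega`. Impact site, after period: `mu1 * omega * gamma`.
#'
#' @param site `"impact"` or `"control"`.
#' @param period `"before"` or `"after"`.
#' @param params A [sim_params()] object.
#' @return Positive scalar mean flight count.
#' @export
cell_flight_mean <- function(site, period, params) {
  if (period == "before") return(params$mu1)
  params$mu1 * params$omega * (if (site == "impact") params$gamma else 1)
}

#' Simulate one paired flight/carcass dataset
#'
#' Draws, for each of the four site x period cells and each of
#' `n_obs_per_cell` search intervals: a true flight count
#' `F ~ NegBin(mean = cell mean, dispersion = theta1)` (generated as a
#' gamma-Poisson mixture for robustness at small `theta1`); a carcass count
#' `C ~ Binomial(F, zeta_cell)` with `zeta_cell = zeta * (1 - lambda)` in
#' the impact-after cell and `zeta` elsewhere; and an observed flight count
#' `O = F` when `detect_prob = 1`, otherwise `O ~ Binomial(F, detect_prob)`
#' drawn independently of the collisions. Each simulated interval spans one
#' day with one observation hour, so the fusion exposure is simply `A = O`.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed; the same seed and parameters
#'   reproduce the dataset exactly.
#' @return A list of class `sim_dataset` with elements `carcass` (tibble
#'   with `site`, `period`, `n_carcass`, `interval_days`, `flights_true`,
#'   usable by [fit_baci()] and [fit_ba()]), `fusion` (impact-site fusion
#'   observation tibble usable by [fit_nb_fusion()] and [fit_b_fusion()])
#'   and `params`.
#' @export
simulate_dataset <- function(params, seed = NULL) {
  if (!inherits(params, "sim_params")) abort("params must come from sim_params()")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- params$n_obs_per_cell
  cells <- expand.grid(period = c("before", "after"),
                       site = c("impact", "control"),
                       stringsAsFactors = FALSE)
  rows <- purrr::pmap(cells, function(period, site) {
    mu <- cell_flight_mean(site, period, params)
    f_true <- rnbinom(n, size = params$theta1, mu = mu)
    zeta_cell <- params$zeta *
      (if (site == "impact" && period == "after") 1 - params$lambda else 1)
    tibble::tibble(
      site = site, period = period,
      flights_true = f_true,
      flights_obs = if (params$detect_prob < 1)
        rbinom(n, f_true, params$detect_prob) else f_true,
      n_carcass = as.numeric(rbinom(n, f_true, zeta_cell)),
      interval_days = 1L
    )
  })
  d <- dplyr::bind_rows(rows)
  fusion <- d |>
    dplyr::filter(.data$site == "impact") |>
    dplyr::transmute(
      period = .data$period,
      n_carcass = .data$n_carcass,
      interval_days = .data$interval_days,
      pooled_individuals = .data$flights_obs,
      pooled_hours = 1,
      exposure_A = as.numeric(.data$flights_obs)
    )
  structure(list(
    carcass = d[c("site", "period", "n_carcass", "interval_days",
                  "flights_true")],
    fusion = fusion,
    params = params
  ), class = "sim_dataset")
}

#' Monte Carlo comparison of the effectiveness estimators
#'
#' Simulates `n_sims` datasets under a scenario, fits the requested
#' estimators to each, and returns one row per dataset x method with the
#' true parameters, the estimated percent reduction, the two-sided Wald
#' p-value and the convergence flag. Non-converged or failed fits are
#' recorded (with `NA` estimates), never dropped silently.
#'
#' @inheritParams scenario_params
#' @param n_sims Number of simulated datasets.
#' @param methods Estimators to fit: subset of `"BA"`, `"BACI"`,
#'   `"NB_fusion"`, `"B_fusion"`.
#' @param omega,gamma,lambda Either a single fixed value, or a length-2
#'   numeric range from which a value is drawn uniformly for every dataset.
#' @param null_fraction Fraction of datasets simulated with `lambda = 0`
#'   (placed first in the output), for false-positive-rate estimation.
#' @param n_obs_per_cell Search intervals per site x period cell.
#' @param seed Master seed; it spawns one independent sub-seed per dataset,
#'   so results are reproducible and any subset of datasets can be re-run.
#' @param b_fusion_c Scaling constant passed to [fit_b_fusion()]; the
#'   default 1 is exact for simulated unit-interval data.
#' @return A tibble with columns `sim_id`, `scenario`, `omega`, `gamma`,
#'   `lambda_true`, `method`, `reduction_est_pct`, `p_value`, `converged`.
#' @export
run_comparison <- function(scenario = c("base", "low_intensity",
                                        "high_variance", "partial_detection"),
                           n_sims,
                           methods = c("BACI", "NB_fusion"),
                           omega = 1, gamma = 1, lambda = 0.5,
                           null_fraction = 0,
                           n_obs_per_cell = 60L,
                           seed = NULL,
                           b_fusion_c = 1) {
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, c("BA", "BACI", "NB_fusion", "B_fusion"),
                       several.ok = TRUE)
  stopifnot(n_sims >= 1, null_fraction >= 0, null_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)

  draw <- function(spec) {
    if (length(spec) == 1L) rep(spec, n_sims)
    else runif(n_sims, spec[1], spec[2])
  }
  omega_i <- draw(omega)
  gamma_i <- draw(gamma)
  lambda_i <- draw(lambda)
  n_null <- round(null_fraction * n_sims)
  if (n_null > 0) lambda_i[seq_len(n_null)] <- 0
  seeds <- sample.int(.Machine$integer.max, n_sims)

  out <- purrr::map(seq_len(n_sims), function(i) {
    p <- scenario_params(scenario, sim_params(
      omega = omega_i[i], gamma = gamma_i[i], lambda = lambda_i[i],
      n_obs_per_cell = n_obs_per_cell))
    d <- simulate_dataset(p, seed = seeds[i])
    fits <- purrr::map(methods, function(m) fit_one_method(m, d, b_fusion_c))
    dplyr::bind_cols(
      tibble::tibble(sim_id = i, scenario = scenario,
                     omega = omega_i[i], gamma = gamma_i[i],
                     lambda_true = lambda_i[i]),
      dplyr::bind_rows(fits)
    )
  })
  dplyr::bind_rows(out)
}

fit_one_method <- function(method, d, b_fusion_c) {
  est <- tryCatch(
    suppressWarnings(switch(method,
      BA = fit_ba(d$carcass),
      BACI = fit_baci(d$carcass),
      NB_fusion = fit_nb_fusion(d$fusion),
      B_fusion = fit_b_fusion(d$fusion, c = b_fusion_c)
    )),
    error = function(e) NULL
  )
  if (is.null(est)) {
    return(tibble::tibble(method = method, reduction_est_pct = NA_real_,
                          p_value = NA_real_, converged = FALSE))
  }
  tibble::tibble(method = method,
                 reduction_est_pct = est$reduction_pct,
                 p_value = est$p_value,
                 converged = est$fit$converged)
}
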