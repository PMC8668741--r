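#' False-positive rate of the estimators
#'
#' Fraction of null simulations (`lambda_true = 0`) declared significant at
#' level `alpha`, per method (and any further grouping columns).
#' Significance is sign-agnostic here: a false positive arises in either
#' direction. Fits with missing p-values (failed or degenerate) count as
#' non-significant, so convergence problems cannot inflate the rate.
#'
#' @param results Results tibble from [run_comparison()] (or several such
#'   tibbles row-bound; all summaries are invariant to row order and file
#'   splits).
#' @param alpha Significance level, default 0.05.
#' @param by Grouping columns, `"method"` by default.
#' @return A tibble with one row per group: `n_sims`, `fpr`,
#'   `mc_standard_error` (binomial, `sqrt(r(1-r)/n)`), and Wilson 95%
#'   interval bounds `ci_low`, `ci_high`.
#' @export
compute_fpr <- function(results, alpha = 0.05, by = "method") {
  nulls <- dplyr::filter(results, .data$lambda_true == 0)
  if (nrow(nulls) == 0L) abort("no null (lambda_true = 0) rows in results")
  nulls |>
    dplyr::mutate(sig = !is.na(.data$p_value) & .data$p_value < alpha) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(rate_summary(.data$sig, "fpr"), .groups = "drop")
}

#' Statistical power of the estimators
#'
#' Fraction of effect simulations (`lambda_true > 0`) declared significant
#' at level `alpha` *with the correct sign* (estimated reduction > 0), per
#' method and grouping columns.
#'
#' @inheritParams compute_fpr
#' @return A tibble as in [compute_fpr()] with a `power` column.
#' @export
compute_power <- function(results, alpha = 0.05, by = "method") {
  eff <- dplyr::filter(results, .data$lambda_true > 0)
  if (nrow(eff) == 0L) abort("no effect (lambda_true > 0) rows in results")
  eff |>
    dplyr::mutate(sig = !is.na(.data$p_value) & .data$p_value < alpha &
                    !is.na(.data$reduction_est_pct) &
                    .data$reduction_est_pct > 0) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(rate_summary(.data$sig, "power"), .groups = "drop")
}

#' Relative bias of the estimated reduction
#'
#' Mean of `(estimated reduction/100 - lambda) / lambda` over effect
#' simulations, per method and grouping columns. Zero means the estimator
#' recovers the true diverter effect on average; negative values mean the
#' effect is understated.
#'
#' @inheritParams compute_fpr
#' @return A tibble with `n_sims`, `relative_bias` and its Monte Carlo
#'   standard error.
#' @export
compute_relative_bias <- function(results, by = "method") {
  eff <- dplyr::filter(results, .data$lambda_true > 0,
                       !is.na(.data$reduction_est_pct))
  if (nrow(eff) == 0L) abort("no effect rows with estimates in results")
  eff |>
    dplyr::mutate(rb = (.data$reduction_est_pct / 100 - .data$lambda_true) /
                    .data$lambda_true) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_sims = dplyr::n(),
      relative_bias = mean(.data$rb),
      mc_standard_error = stats::sd(.data$rb) / sqrt(dplyr::n()),
      .groups = "drop")
}

#' Power ratio between two estimators over a reduction grid
#'
#' Computes each method's power separately at every simulated value of the
#' true reduction `lambda_true`, averages the powers over the grid, and
#' returns the ratio of the averages (numerator / denominator). This is the
#' summary used to state, e.g., a "3-fold higher power" of the fusion
#' design over BACI in the unbiased scenario.
#'
#' @inheritParams compute_fpr
#' @param numerator,denominator Method names present in `results`.
#' @return A scalar ratio; an average denominator power of zero yields
#'   `Inf` with a warning.
#' @export
power_ratio <- function(results, numerator = "NB_fusion",
                        denominator = "BACI", alpha = 0.05) {
  pw <- compute_power(results, alpha, by = c("method", "lambda_true"))
  grid <- unique(pw$lambda_true)
  mean_power <- function(m) {
    pm <- dplyr::filter(pw, .data$method == m)
    if (!setequal(pm$lambda_true, grid)) {
      abort(paste0("method '", m, "' missing from some grid points"))
    }
    mean(pm$power)
  }
  num <- mean_power(numerator)
  den <- mean_power(denominator)
  if (den == 0) {
    warn("denominator method has zero average power; ratio is infinite")
    return(Inf)
  }
  num / den
}

#' Performance along one simulation parameter
#'
#' Evaluates a performance metric at each simulated value (slice) of one
#' parameter, per method: the empirical analogue of plotting power,
#' false-positive rate or relative bias against the synchronicity violation,
#' the flight-intensity change, or the true reduction strength, with the
#' remaining parameters held fixed by the simulation design.
#'
#' @inheritParams compute_fpr
#' @param variable One of `"omega"`, `"gamma"`, `"lambda_true"`.
#' @param metric One of `"power"`, `"fpr"`, `"bias"`.
#' @return A tibble with one row per method x slice value carrying the
#'   metric and its uncertainty (Wilson 95% interval for rates, +-
#'   standard error for bias).
#' @export
performance_curve <- function(results, variable = c("gamma", "omega",
                                                    "lambda_true"),
                              metric = c("power", "fpr", "bias"),
                              alpha = 0.05) {
  variable <- match.arg(variable)
  metric <- match.arg(metric)
  by <- c("method", variable)
  out <- switch(metric,
    power = compute_power(results, alpha, by = by),
    fpr = compute_fpr(results, alpha, by = by),
    bias = compute_relative_bias(results, by = by)
  )
  dplyr::rename(out, value = dplyr::all_of(variable))
}

#' Plot a performance curve
#'
#' @param curve Output of [performance_curve()].
#' @return A ggplot object: metric against the sliced parameter, one line
#'   per method, with its uncertainty band.
#' @export
plot_performance <- function(curve) {
  metric <- intersect(c("power", "fpr", "relative_bias"), names(curve))[1]
  p <- ggplot2::ggplot(curve, ggplot2::aes(
    x = .data$value, y = .data[[metric]],
    colour = .data$method, group = .data$method))
  if (all(c("ci_low", "ci_high") %in% names(curve))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                   fill = .data$method),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

# --- internal ---------------------------------------------------------------

rate_summary <- function(sig, name) {
  n <- length(sig)
  r <- mean(sig)
  w <- wilson_interval(sum(sig), n)
  out <- tibble::tibble(
    n_sims = n, rate = r,
    mc_standard_error = sqrt(r * (1 - r) / n),
    ci_low = w[1], ci_high = w[2])
  names(out)[names(out) == "rate"] <- name
  out
}

wilson_interval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  d <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / d
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / d
  c(max(0, centre - half), min(1, centre + half))
}
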