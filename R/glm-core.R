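#' Fit a negative binomial regression with log link
#'
#' Maximum-likelihood fit of a negative binomial GLM parameterized by
#' variance = mu + mu^2/theta (so small `theta` means strong
#' overdispersion). Coefficients are estimated by iteratively reweighted
#' least squares given `theta`, alternated with one-dimensional profile
#' maximization of the likelihood over `theta`. The log-likelihood is
#' evaluated through gamma functions, so non-integer responses — such as
#' detectability-corrected carcass counts — are admissible.
#'
#' @param x Numeric design matrix with named columns (include the intercept
#'   column explicitly); must have full column rank.
#' @param y Non-negative numeric response vector.
#' @param offset Optional numeric offset on the log scale (defaults to 0).
#' @param theta Optional fixed dispersion; if `NULL` (default) `theta` is
#'   profiled out by maximum likelihood, with a method-of-moments
#'   initializer.
#' @param max_iter Maximum number of outer (coefficient/theta) iterations.
#'
#' @return An object of class `fusion_glm`: a list with elements
#'   `coefficients`, `vcov` (conditional on the fitted `theta`), `theta`,
#'   `log_lik`, `converged`, `n_iter`, `residuals` (deviance scale),
#'   `fitted`, `family`, `nobs`.
#'
#' @details Convergence requires the max-norm change in coefficients to fall
#'   below 1e-8 and the relative change in `theta` below 1e-6. `theta` is
#'   capped at 1e7; data with no residual overdispersion push `theta` to the
#'   cap, where the fit coincides with the Poisson fit. An all-zero response
#'   leaves the model unidentifiable and is an error.
#' @seealso [fit_binomial()], [wald_inference()]
#' @export
fit_negbin <- function(x, y, offset = NULL, theta = NULL, max_iter = 50L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(y < 0)) abort("negative response in negative binomial fit")
  if (sum(y) == 0) abort("all-zero response: model unidentifiable")
  if (length(y) != nrow(x)) abort("response length != design rows")
  offset <- offset %||% rep(0, length(y))
  if (qr(x)$rank < ncol(x)) abort("design matrix is rank deficient")

  theta_cap <- 1e7
  fixed_theta <- !is.null(theta)

  # Poisson start for the mean structure
  fit <- suppressWarnings(glm.fit(x, y, offset = offset, family = poisson()))
  mu <- fit$fitted.values
  if (!fixed_theta) {
    num <- sum((y - mu)^2 - mu)
    theta <- if (num > 0) min(max(sum(mu^2) / num, 1e-3), theta_cap) else theta_cap
  }

  beta <- coef(fit)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fit <- suppressWarnings(glm.fit(
      x, y, offset = offset, start = beta,
      family = MASS::negative.binomial(theta),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100L)))
    beta_new <- coef(fit)
    mu <- fit$fitted.values
    theta_new <- if (fixed_theta) theta else
      profile_theta(y, mu, theta, cap = theta_cap)
    db <- max(abs(beta_new - beta))
    dt <- abs(theta_new - theta) / max(1, abs(theta))
    beta <- beta_new
    theta <- theta_new
    if (db < 1e-8 && dt < 1e-6) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("negative binomial fit did not converge in %d iterations", iter))
  }

  structure(list(
    coefficients = setNames(beta, colnames(x)),
    vcov = glmfit_vcov(fit, colnames(x)),
    theta = theta,
    log_lik = negbin_loglik(y, mu, theta),
    converged = converged,
    n_iter = iter,
    residuals = fit$residuals * sqrt(fit$weights),
    fitted = mu,
    family = "negbin",
    nobs = length(y)
  ), class = "fusion_glm")
}

#' Fit a binomial (events/non-events) regression with logit link
#'
#' Maximum-likelihood logistic regression for grouped binomial responses,
#' fitted by iteratively reweighted least squares.
#'
#' @inheritParams fit_negbin
#' @param events,nonevents Non-negative integer vectors; `events + nonevents`
#'   must be positive in every row.
#' @return A `fusion_glm` object (see [fit_negbin()]); `theta` is `NA` for
#'   the binomial family. Complete separation (fitted probabilities pinned
#'   at 0 or 1) is flagged through `converged = FALSE`.
#' @export
fit_binomial <- function(x, events, nonevents, offset = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  trials <- events + nonevents
  if (any(events < 0 | nonevents < 0)) abort("negative binomial-family counts")
  if (any(trials <= 0)) abort("rows with zero trials: drop them before fitting")
  offset <- offset %||% rep(0, length(events))

  fit <- suppressWarnings(glm.fit(
    x, events / trials, weights = trials, offset = offset,
    family = stats::binomial()))
  p <- fit$fitted.values
  separated <- any(p < 1e-10 | p > 1 - 1e-10)
  if (separated) warn("complete or quasi-complete separation detected")

  structure(list(
    coefficients = setNames(coef(fit), colnames(x)),
    vcov = glmfit_vcov(fit, colnames(x)),
    theta = NA_real_,
    log_lik = sum(dbinom(round(events), round(trials), p, log = TRUE)),
    converged = fit$converged && !separated,
    n_iter = fit$iter,
    residuals = fit$residuals * sqrt(fit$weights),
    fitted = p,
    family = "binomial",
    nobs = length(events)
  ), class = "fusion_glm")
}

#' Wald inference for one coefficient
#'
#' Point estimate, standard error, z statistic, two-sided normal p-value and
#' confidence interval for a named coefficient, all on the link scale.
#'
#' @param fit A `fusion_glm` object.
#' @param coefficient Name of the coefficient.
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `ci_low`, `ci_high`.
#' @export
wald_inference <- function(fit, coefficient, level = 0.95) {
  if (!coefficient %in% names(fit$coefficients)) {
    abort(paste0("no coefficient named '", coefficient, "'"))
  }
  est <- fit$coefficients[[coefficient]]
  v <- fit$vcov[coefficient, coefficient]
  if (!is.finite(v) || v <= 0) abort("degenerate coefficient variance")
  se <- sqrt(v)
  z <- est / se
  q <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = coefficient, estimate = est, std_error = se, statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    ci_low = est - q * se, ci_high = est + q * se
  )
}

#' Cyclic cubic B-spline basis for day of year
#'
#' Builds a periodic cubic B-spline basis on the day-of-year axis for
#' seasonal adjustment of survey models. The basis has period 365 days (day
#' 366 of a leap year aliases day 1), equally spaced knots, and matches
#' value, first and second derivative across the year seam. Columns are
#' mean-centered by default so the basis does not confound the intercept.
#'
#' @param jday Integer day of year, values in 1..366.
#' @param n_basis Number of basis functions (>= 3), default 8.
#' @param center Prepare the basis for use next to an intercept? The raw
#'   periodic basis sums to 1 in every row (B-spline partition of unity), so
#'   it contains the constant function; `center = TRUE` mean-centers the
#'   columns and drops the last one, leaving `n_basis - 1` identifiable
#'   columns spanning the seasonal (non-constant) part.
#' @return A numeric matrix with `length(jday)` rows and `n_basis`
#'   (`center = FALSE`) or `n_basis - 1` (`center = TRUE`) columns named
#'   `jday_s1`, `jday_s2`, ...
#' @export
cyclic_spline_basis <- function(jday, n_basis = 8L, center = TRUE) {
  if (n_basis < 3L) abort("cyclic spline needs at least 3 basis functions")
  period <- 365
  t <- (as.numeric(jday) - 1) %% period
  h <- period / n_basis
  knots <- seq(-3 * h, period + 3 * h, by = h)
  B <- splines::splineDesign(knots, t, ord = 4L)
  B[, 1:3] <- B[, 1:3] + B[, n_basis + 1:3]
  B <- B[, seq_len(n_basis), drop = FALSE]
  if (center) {
    B <- sweep(B, 2L, colMeans(B))[, seq_len(n_basis - 1L), drop = FALSE]
  }
  colnames(B) <- paste0("jday_s", seq_len(ncol(B)))
  B
}

# --- internal ---------------------------------------------------------------

# NB log-likelihood with continuous gamma-function evaluation, valid for
# non-integer y (lgamma(y + 1) extends the factorial).
negbin_loglik <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) +
        ifelse(y > 0, y * log(mu / (theta + mu)), 0))
}

# One-dimensional profile maximization over log(theta). Data without
# residual overdispersion make the profile flat towards theta = Inf; the
# cap is returned whenever it is not measurably worse than the optimum,
# which pins the Poisson limit instead of letting theta jitter below it.
profile_theta <- function(y, mu, theta, cap) {
  lt <- log(theta)
  f <- function(l) negbin_loglik(y, mu, exp(l))
  for (k in 1:6) {
    opt <- optimize(f, c(lt - 4, lt + 4), maximum = TRUE, tol = 1e-10)
    if (abs(opt$maximum - lt) < 3.9 || exp(opt$maximum) >= cap) break
    lt <- opt$maximum
  }
  if (f(log(cap)) >= opt$objective - 1e-7) return(cap)
  min(exp(opt$maximum), cap)
}

# (X' W X)^{-1} from the final IRLS step, honoring column pivoting.
glmfit_vcov <- function(fit, nms) {
  p <- fit$rank
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  V <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(p)]
  out <- matrix(NA_real_, length(nms), length(nms), dimnames = list(nms, nms))
  out[piv, piv] <- V
  out
}

#' @export
print.fusion_glm <- function(x, ...) {
  cat("<fusion_glm>", x$family, "fit,", x$nobs, "observations\n")
  print(x$coefficients)
  if (x$family == "negbin") cat("theta:", format(x$theta), "\n")
  cat("log-likelihood:", format(x$log_lik),
      if (!x$converged) "(NOT converged)" else "", "\n")
  invisible(x)
}
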