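# Independent oracle: generic optimizer maximization of the model
# likelihoods, written with stats::dnbinom / dbinom rather than the
# package's IRLS fitting path.

oracle_negbin <- function(x, y, offset = rep(0, length(y))) {
  nll <- function(par) {
    mu <- exp(drop(x %*% par[-length(par)]) + offset)
    -sum(dnbinom(y, size = exp(par[length(par)]), mu = mu, log = TRUE))
  }
  start <- c(rep(0, ncol(x)), 0)
  opt <- optim(start, nll, method = "BFGS", control = list(maxit = 500))
  list(beta = opt$par[-length(opt$par)], theta = exp(opt$par[length(opt$par)]))
}

oracle_binomial <- function(x, events, nonevents) {
  n <- events + nonevents
  nll <- function(beta) {
    p <- stats::plogis(drop(x %*% beta))
    -sum(dbinom(events, n, p, log = TRUE))
  }
  optim(rep(0, ncol(x)), nll, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

two_group_design <- function(n) {
  cbind(`(Intercept)` = 1, group = rep(c(0, 1), each = n / 2))
}
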