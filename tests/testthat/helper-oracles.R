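# Independent oracles used across the suite.

# Damped Newton maximization of the Poisson log-likelihood with offset:
# a from-scratch optimizer, deliberately not sharing any code with
# fit_poisson's IRLS path.
newton_poisson <- function(X, D, offset, tol = 1e-12, maxit = 200) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  loglik <- function(b) {
    eta <- drop(X %*% b) + offset
    sum(D * eta - exp(eta))
  }
  ll <- loglik(beta)
  for (it in seq_len(maxit)) {
    mu <- exp(drop(X %*% beta) + offset)
    grad <- drop(crossprod(X, D - mu))
    hess <- crossprod(X, X * mu)
    step <- solve(hess, grad)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- loglik(cand)
      if (llc >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-12) stop("newton oracle: step collapse")
    }
    done <- abs(llc - ll) < tol * (abs(ll) + 1)
    beta <- cand
    ll <- llc
    if (done) break
  }
  mu <- exp(drop(X %*% beta) + offset)
  dev <- 2 * sum(ifelse(D > 0, D * log(D / mu), 0) - (D - mu))
  list(coef = beta, deviance = dev, loglik = ll)
}

# chi-square upper tail by numerical integration of the density
chisq_upper_quadrature <- function(q, df) {
  stats::integrate(function(x) stats::dchisq(x, df), lower = q, upper = Inf,
                   rel.tol = 1e-12)$value
}

# expected identifiable curvature of a generating effect vector: the
# unweighted least-squares detrended component, re-zeroed at the reference
expected_curvature <- function(eff, ref) {
  n <- length(eff)
  X <- cbind(1, seq_len(n))
  res <- eff - drop(X %*% solve(crossprod(X), crossprod(X, eff)))
  res - res[ref]
}

# small clean configuration for fast simulation-based tests
small_config <- function(seed, ...) {
  args <- list(n_age_groups = 4L, n_periods = 3L,
               population_base = 1e4,
               p_ill_defined = 0, p_incomplete = 0,
               completeness = c("1980" = 1, "1990" = 1),
               frac_other_cancer = 1, frac_other_natural = 2,
               frac_non_natural = 0.5, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

unit_factors <- function() {
  correction_factors(c("1980" = 1, "1990" = 1, "2000" = 1, "2010" = 1))
}

# grid whose cell means satisfy an exact log-linear APC structure
exact_grid <- function(config) {
  rate <- generate_true_rates(config)
  N <- matrix(config$population_base, nrow(rate), ncol(rate))
  mortality_grid(N * rate, N, config$age_starts, config$period_starts)
}
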