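#' Poisson regression with log link and person-years offset
#'
#' Maximum-likelihood fit of `D ~ Poisson(N * exp(X beta))` via iteratively
#' reweighted least squares.  Corrected death counts may be real-valued;
#' the deviance is the usual `2 * sum(d*log(d/mu) - (d - mu))` which
#' extends smoothly to non-integer `d`.
#'
#' @param X numeric model matrix (including the intercept column).
#' @param D response: death counts per cell, real-valued allowed.
#' @param offset log person-years per cell.
#' @param epsilon relative deviance convergence tolerance (default 1e-10).
#' @param maxit maximum IRLS iterations (default 100); non-convergence is
#'   an error, never a silent result.
#' @return list with `coef`, `cov` (inverse observed information),
#'   `deviance`, `df` (residual degrees of freedom), `fitted` (cell means)
#'   and `rank`.
#' @export
fit_poisson <- function(X, D, offset, epsilon = 1e-10, maxit = 100L) {
  X <- as.matrix(X)
  if (length(D) != nrow(X) || length(offset) != nrow(X))
    stop("X, D and offset must agree in length")
  if (any(D < 0)) stop("death counts must be non-negative")
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = D, offset = offset, family = stats::poisson(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  if (!fit$converged)
    stop(sprintf("Poisson fit did not converge in %d iterations", maxit))
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "),
         " (unconstrained age-period-cohort terms are exactly collinear)")
  }
  w <- fit$weights
  info <- crossprod(X, X * w)
  covb <- solve(info)
  dimnames(covb) <- list(colnames(X), colnames(X))
  list(coef = stats::coef(fit), cov = covb,
       deviance = fit$deviance, df = fit$df.residual,
       fitted = fit$fitted.values, rank = fit$rank)
}

#' Relative risks with Wald confidence intervals
#'
#' @param coef log relative risk(s).
#' @param se standard error(s) on the log scale, `>= 0`.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `RR`, `lo`, `hi`.
#' @examples
#' rr_with_ci(log(2), 0.1)
#' @export
rr_with_ci <- function(coef, se, level = 0.95) {
  if (any(se < 0)) stop("standard errors must be non-negative")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(RR = exp(coef), lo = exp(coef - z * se), hi = exp(coef + z * se))
}

#' Fit the age-period-cohort Poisson model with estimable reporting
#'
#' Fits `log E[D_ij] = log N_ij + f(age) + drift * (j - j_ref) +
#' period_curvature(j) + cohort_curvature(k)` and reports only estimable
#' quantities: the net drift (the common linear time trend, per 5-year
#' step and annualized), the longitudinal age curve (fitted rates along
#' the reference cohort, curvatures at zero), and period and cohort
#' effects as relative risks that equal 1 exactly at the reference period
#' and reference cohort.  By default period and cohort are reported as
#' pure curvatures (zero slope); `drift_to` re-allocates the fitted linear
#' trend onto the period or the cohort table for comparison with other
#' software conventions — the fitted cell means are identical under every
#' allocation.
#'
#' @param grid a [mortality_grid()].
#' @param design an [apc_design()]; defaults to the design implied by the
#'   grid's age and period labels.
#' @param model one of `"apc"` (default), `"age"`, `"age-drift"`,
#'   `"age-period"`, `"age-cohort"`.
#' @param drift_to `"none"` (curvature-only tables, default), `"period"`,
#'   or `"cohort"`.
#' @param level confidence level for Wald intervals.
#' @return An object of class `apc_fit` with elements `drift` (per-5yr and
#'   annual estimate, se and CI), `age` (longitudinal age curve, rates per
#'   100,000), `period` and `cohort` (log-RR, se, RR, CI), `deviance`,
#'   `df`, `fitted` (I x J matrix of cell means), `coef`, `cov`, `design`.
#' @export
fit_apc <- function(grid, design = NULL, model = "apc",
                    drift_to = c("none", "period", "cohort"),
                    level = 0.95) {
  stopifnot(is_mortality_grid(grid))
  drift_to <- match.arg(drift_to)
  if (is.null(design))
    design <- apc_design(grid$age_starts, grid$period_starts)
  fr <- apc_frame(grid, design)
  X <- apc_model_matrix(design, model, fr)
  fp <- fit_poisson(X, fr$D, log(fr$N))
  Bp <- attr(X, "period_basis")
  Bk <- attr(X, "cohort_basis")
  p <- length(fp$coef)
  cn <- colnames(X)

  has_drift <- "drift" %in% cn
  drift <- NULL
  if (has_drift) {
    d <- fp$coef[["drift"]]
    se <- sqrt(fp$cov["drift", "drift"])
    z <- stats::qnorm(1 - (1 - level) / 2)
    drift <- list(per5 = d, se_per5 = se,
                  lo_per5 = d - z * se, hi_per5 = d + z * se,
                  annual = d / 5, se_annual = se / 5,
                  lo_annual = (d - z * se) / 5, hi_annual = (d + z * se) / 5)
  }

  # contrast rows over the full coefficient vector for one category of a
  # time effect: curvature difference to the reference, plus the drift
  # column when the linear trend is allocated to this dimension
  effect_table <- function(B, idx_cols, ref, starts, allocate) {
    n <- nrow(B)
    L <- matrix(0, n, p, dimnames = list(NULL, cn))
    if (length(idx_cols))
      L[, idx_cols] <- sweep(B, 2, B[ref, ], "-")
    if (allocate && has_drift)
      L[, "drift"] <- seq_len(n) - ref
    est <- drop(L %*% fp$coef)
    se <- sqrt(pmax(0, rowSums((L %*% fp$cov) * L)))
    rr <- rr_with_ci(est, se, level)
    data.frame(start = starts, logRR = est, se = se, rr)
  }

  period <- cohort <- NULL
  pc <- grep("^per\\.", cn)
  kc <- grep("^coh\\.", cn)
  if (model %in% c("apc", "age-period"))
    period <- effect_table(Bp, cn[pc], design$ref_j,
                           design$period_starts, drift_to == "period")
  if (model %in% c("apc", "age-cohort"))
    cohort <- effect_table(Bk, cn[kc], design$ref_k,
                           design$cohort_starts, drift_to == "cohort")

  # longitudinal age curve: fitted log rate at age i along the reference
  # cohort (j = ref_k - I + i, linear extrapolation of the drift outside
  # the observed period range), curvature terms held at zero
  Ba <- attr(X, "age_basis")
  La <- matrix(0, design$I, p, dimnames = list(NULL, cn))
  La[, colnames(Ba)] <- Ba
  if (has_drift)
    La[, "drift"] <- (design$ref_k - design$I + seq_len(design$I)) - design$ref_j
  a_est <- drop(La %*% fp$coef)
  a_se <- sqrt(pmax(0, rowSums((La %*% fp$cov) * La)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  age <- data.frame(age_start = design$age_starts,
                    log_rate = a_est, se = a_se,
                    rate_per_100k = 1e5 * exp(a_est),
                    lo = 1e5 * exp(a_est - z * a_se),
                    hi = 1e5 * exp(a_est + z * a_se))
  # longitudinal age slope (per 5-year age step): OLS slope of the curve
  age_slope <- unname(stats::coef(stats::lm(a_est ~ seq_len(design$I)))[2])

  structure(
    list(model = model, design = design, drift_to = drift_to,
         coef = fp$coef, cov = fp$cov,
         deviance = fp$deviance, df = fp$df,
         fitted = matrix(fp$fitted, design$I, design$J,
                         dimnames = dimnames(grid$D)),
         drift = drift, age = age, age_slope = age_slope,
         period = period, cohort = cohort, level = level),
    class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf("<apc_fit> model %s (%s parameterization)\n",
              x$model, x$design$mode))
  cat(sprintf("  residual deviance %.3f on %d df\n", x$deviance, x$df))
  if (!is.null(x$drift))
    cat(sprintf("  net drift: %.4f per 5 years (annual %.4f, %d%% CI %.4f to %.4f)\n",
                x$drift$per5, x$drift$annual, round(100 * x$level),
                x$drift$lo_annual, x$drift$hi_annual))
  if (!is.null(x$period))
    cat(sprintf("  period RR range %.3f-%.3f (ref %d-%d)\n",
                min(x$period$RR), max(x$period$RR),
                x$design$ref_period, x$design$ref_period + 4L))
  if (!is.null(x$cohort))
    cat(sprintf("  cohort RR range %.3f-%.3f (ref %d-%d)\n",
                min(x$cohort$RR), max(x$cohort$RR),
                x$design$ref_cohort, x$design$ref_cohort + 4L))
  invisible(x)
}

#' Net drift of a fitted model
#'
#' The common linear trend of the log rates — the sum of the period and
#' cohort slopes — per 5-year step and annualized, with its Wald CI.
#'
#' @param fit an [fit_apc()] result whose model contains a drift term.
#' @return list with elements `per5`, `annual`, each `(estimate, lo, hi)`.
#' @export
extract_drift <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  if (is.null(fit$drift))
    stop("model '", fit$model, "' has no drift term; drift is undefined")
  d <- fit$drift
  list(per5 = c(estimate = d$per5, lo = d$lo_per5, hi = d$hi_per5),
       annual = c(estimate = d$annual, lo = d$lo_annual, hi = d$hi_annual))
}

#' Export an APC fit as tidy tables
#'
#' @param fit an `apc_fit`.
#' @return list of data frames (`age`, `period`, `cohort`, `drift`,
#'   `fit_stats`) suitable for writing as CSV/JSON.
#' @export
apc_fit_tables <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  drift <- if (is.null(fit$drift)) NULL else
    data.frame(scale = c("per_5yr", "annual"),
               estimate = c(fit$drift$per5, fit$drift$annual),
               lo = c(fit$drift$lo_per5, fit$drift$lo_annual),
               hi = c(fit$drift$hi_per5, fit$drift$hi_annual))
  list(age = fit$age, period = fit$period, cohort = fit$cohort,
       drift = drift,
       fit_stats = data.frame(model = fit$model,
                              deviance = fit$deviance, df = fit$df))
}
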