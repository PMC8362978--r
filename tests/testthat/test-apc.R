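test_that("cohort indexing spans K = I + J - 1 diagonals", {
  expect_equal(cohort_index(13, 1, 13), 1L)
  expect_equal(cohort_index(1, 8, 13), 20L)
  expect_equal(cohort_index(1, 1, 13), 13L)
  expect_error(cohort_index(14, 1, 13), "out of range")
  d <- apc_design()
  expect_equal(d$K, 20L)
  expect_equal(range(d$cohort_starts), c(1900L, 1995L))
  expect_equal(d$cohort_starts[d$ref_k], 1945L)
  expect_equal(d$period_starts[d$ref_j], 1995L)
})

test_that("fit_poisson recovers saturating and closed-form inputs", {
  # age-only model with exactly log-linear means: zero deviance and exact
  # coefficient recovery
  I <- 5; J <- 3
  mu <- -7; alpha <- c(0, 0.4, 0.9, 1.3, 1.6)
  N <- matrix(2e5, I, J)
  D <- N * exp(mu + alpha)          # recycles alpha down columns
  fr <- data.frame(i = rep(1:I, J))
  X <- cbind(1, stats::contr.treatment(I)[fr$i, ])
  fit <- fit_poisson(X, as.vector(D), log(as.vector(N)))
  expect_lt(fit$deviance, 1e-6)
  expect_equal(unname(fit$coef), c(mu, alpha[-1]), tolerance = 1e-7)

  # intercept-only on a single cell: rate = D / N in closed form
  fit1 <- fit_poisson(matrix(1, 1, 1), 10, log(1000))
  expect_equal(unname(exp(fit1$coef)), 0.01, tolerance = 1e-9)

  # exact collinearity is reported as an identifiability error
  Xbad <- cbind(a = c(1, 1, 1, 1), b = c(1, 0, 1, 0), c = c(0, 1, 0, 1))
  expect_error(fit_poisson(Xbad, c(3, 4, 5, 6), rep(0, 4)),
               "rank deficient.*aliased")
})

test_that("deviances agree with an independent Newton maximization on small grids", {
  set.seed(42)
  for (rep in 1:10) {
    des <- apc_design(age_starts = seq(40, 55, 5),
                      period_starts = seq(1980, 1990, 5),
                      ref_period = 1985, ref_cohort = 1945)
    N <- matrix(runif(12, 5e4, 2e5), 4, 3)
    D <- matrix(rpois(12, lambda = N * exp(rnorm(12, -8, 0.3))), 4, 3)
    g <- mortality_grid(D, N, des$age_starts, des$period_starts)
    fr <- apcmort:::apc_frame(g, des)
    for (model in c("age", "age-drift", "age-period", "age-cohort", "apc")) {
      X <- apcmort:::apc_model_matrix(des, model, fr)
      ours <- fit_poisson(X, fr$D, log(fr$N))
      oracle <- newton_poisson(X, fr$D, log(fr$N))
      expect_lt(abs(ours$deviance - oracle$deviance), 1e-6)
    }
  }
})

test_that("relative risks and Wald intervals are exponentiated contrasts", {
  rr <- rr_with_ci(0, 0.1)
  expect_equal(rr$RR, 1)
  expect_equal(rr$lo, exp(-1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(rr$hi, exp(+1.959964 * 0.1), tolerance = 1e-6)
  expect_equal(round(c(rr$lo, rr$hi), 3), c(0.822, 1.217))
  rr0 <- rr_with_ci(log(2), 0)
  expect_equal(c(rr0$RR, rr0$lo, rr0$hi), rep(2, 3))
  expect_error(rr_with_ci(0, -1), "non-negative")
})

test_that("drift and curvatures are recovered exactly on expectation-valued input", {
  des <- apc_design()

  # pure age structure: no drift
  cfg <- synthetic_config(period_effects = rep(0, 8), cohort_effects = rep(0, 20))
  f <- fit_apc(exact_grid(cfg), des)
  expect_lt(abs(f$drift$per5), 1e-6)
  expect_lt(f$deviance, 1e-6)

  # pure drift 0.05 per 5-year period: annualized 0.01, no curvature
  cfg <- synthetic_config(period_effects = 0.05 * (seq_len(8) - des$ref_j),
                          cohort_effects = rep(0, 20))
  f <- fit_apc(exact_grid(cfg), des)
  expect_equal(f$drift$per5, 0.05, tolerance = 1e-8)
  expect_equal(f$drift$annual, 0.01, tolerance = 1e-8)
  expect_lt(max(abs(f$period$logRR)), 1e-6)
  expect_lt(max(abs(f$cohort$logRR)), 1e-6)

  # drift laid on the cohort axis is the same estimable quantity
  cfg <- synthetic_config(period_effects = rep(0, 8),
                          cohort_effects = 0.05 * (seq_len(20) - des$ref_k))
  f <- fit_apc(exact_grid(cfg), des)
  expect_equal(f$drift$per5, 0.05, tolerance = 1e-8)

  # curvatures: fitted period/cohort effects equal the detrended
  # generating vectors re-zeroed at the references
  cfg <- synthetic_config()
  f <- fit_apc(exact_grid(cfg), des)
  expect_equal(f$period$logRR,
               expected_curvature(cfg$period_effects, des$ref_j),
               tolerance = 1e-6)
  expect_equal(f$cohort$logRR,
               expected_curvature(cfg$cohort_effects, des$ref_k),
               tolerance = 1e-6)

  # references are pinned at RR = 1 exactly, with zero-width intervals
  expect_identical(f$period$RR[des$ref_j], 1)
  expect_identical(f$cohort$RR[des$ref_k], 1)
  expect_equal(f$period$se[des$ref_j], 0)

  # on a curvature-free surface the APC drift coincides with the slope of
  # the age-drift sub-model fitted to the same data (with curvature in the
  # truth the two weight cells differently and need not agree exactly)
  cfgd <- synthetic_config(period_effects = 0.04 * (seq_len(8) - des$ref_j),
                           cohort_effects = rep(0, 20))
  fa <- fit_apc(exact_grid(cfgd), des)
  fd <- fit_apc(exact_grid(cfgd), des, model = "age-drift")
  expect_equal(fa$drift$per5, fd$drift$per5, tolerance = 1e-6)
  expect_equal(fd$drift$per5, 0.04, tolerance = 1e-8)
})

test_that("fitted cell means are invariant to how the linear trend is allocated", {
  cfg <- synthetic_config(seed = 77)
  g <- synthetic_grid(cfg)
  f0 <- fit_apc(g, drift_to = "none")
  fp <- fit_apc(g, drift_to = "period")
  fc <- fit_apc(g, drift_to = "cohort")
  expect_lt(max(abs(fp$fitted - f0$fitted) / f0$fitted), 1e-8)
  expect_lt(max(abs(fc$fitted - f0$fitted) / f0$fitted), 1e-8)
  # deviance and curvature contrasts unchanged; only the trend moves
  expect_equal(fp$deviance, fc$deviance, tolerance = 1e-10)
  # allocated tables differ from curvature-only tables by the linear term
  des <- f0$design
  lin <- f0$drift$per5 * (seq_len(des$J) - des$ref_j)
  expect_equal(fp$period$logRR, f0$period$logRR + lin, tolerance = 1e-8)
})

test_that("drift is undefined for the age-only model", {
  cfg <- synthetic_config(seed = 3)
  f <- fit_apc(synthetic_grid(cfg), model = "age")
  expect_error(extract_drift(f), "undefined")
})

test_that("parameter recovery: estimable quantities within 3 SE on stochastic grids", {
  des <- apc_design()
  gen_drift <- 0.05  # default generator: cohort slope 0.05 per 5-year index
  hits <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(seed = 1000 + s)
    f <- fit_apc(synthetic_grid(cfg), des)
    # drift within 3 SE of the generating linear trend
    gen <- local({
      # generating net drift: OLS slope of (period + cohort) linear parts
      pslope <- stats::coef(stats::lm(cfg$period_effects ~ seq_len(8)))[2]
      cslope <- stats::coef(stats::lm(cfg$cohort_effects ~ seq_len(20)))[2]
      unname(pslope + cslope)
    })
    if (abs(f$drift$per5 - gen) <= 3 * f$drift$se_per5) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("spline parameterization fits with reduced df and keeps references pinned", {
  cfg <- synthetic_config(seed = 21)
  g <- synthetic_grid(cfg)
  des <- apc_design(mode = "spline", spline_df = c(age = 8, period = 5, cohort = 6))
  f <- fit_apc(g, des)
  ffac <- fit_apc(g)
  expect_gt(f$df, ffac$df)          # smoother model spends fewer parameters
  expect_identical(f$period$RR[des$ref_j], 1)
  expect_identical(f$cohort$RR[des$ref_k], 1)
  expect_gte(f$deviance, ffac$deviance - 1e-8)  # factor model is the richest
})

test_that("grids with empty person-year cells are rejected", {
  expect_error(mortality_grid(matrix(1, 2, 2), matrix(c(0, 1, 1, 1), 2, 2)),
               "strictly positive")
})
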