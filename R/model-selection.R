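#' Likelihood-ratio (deviance) test between nested Poisson models
#'
#' Upper-tail chi-square probability of the deviance difference on the
#' difference in residual degrees of freedom.
#'
#' @param dev_reduced,df_reduced deviance and residual df of the smaller
#'   model.
#' @param dev_full,df_full deviance and residual df of the larger model.
#' @return p-value in [0, 1]; `NA` when the df difference is zero.
#' @examples
#' lrt(103.84, 96, 100.0, 95)  # delta deviance 3.84 on 1 df ~ 0.05
#' @export
lrt <- function(dev_reduced, df_reduced, dev_full, df_full) {
  if (df_reduced < df_full)
    stop("the reduced model must not have fewer residual df than the full")
  ddev <- dev_reduced - dev_full
  if (ddev < -1e-8)
    stop("deviance increased in the larger model: the models are not nested")
  ddev <- max(ddev, 0)
  ddf <- df_reduced - df_full
  if (ddf == 0) return(NA_real_)
  stats::pchisq(ddev, df = ddf, lower.tail = FALSE)
}

#' Sequential deviance table of the nested age-period-cohort sub-models
#'
#' Fits the five sub-models (age; age-drift; age-cohort; full
#' age-period-cohort; age-period) and arranges them in the conventional
#' six-row sequence — Age, Age-drift, Age-Cohort, Age-Period-Cohort,
#' Age-Period, Age-drift — where each row's p-value tests it against the
#' adjacent previous row, so the drift row appears twice (a single shared
#' fit) and the final drift row is tested against Age-Period.
#'
#' A "best model" is also reported: the smallest adequate model by the
#' adjacent-line tests at `alpha` — the full model when both the period
#' and the cohort curvature contribute; otherwise age-cohort or
#' age-period when only one does; age-drift when only the common linear
#' trend is needed; and the pure age model otherwise.
#'
#' @param grid a [mortality_grid()].
#' @param design an [apc_design()] (defaults to the grid's own lattice).
#' @param alpha significance level for the selection rule (default 0.05).
#' @return data frame of class `apc_model_table` with columns `model`,
#'   `df`, `deviance`, `p_value`, and attributes `best_model` and
#'   `deviances` (named, one per distinct sub-model).
#' @export
sequential_table <- function(grid, design = NULL, alpha = 0.05) {
  stopifnot(is_mortality_grid(grid))
  if (is.null(design))
    design <- apc_design(grid$age_starts, grid$period_starts)
  fr <- apc_frame(grid, design)
  off <- log(fr$N)
  dev_df <- function(model) {
    f <- fit_poisson(apc_model_matrix(design, model, fr), fr$D, off)
    c(dev = f$deviance, df = f$df)
  }
  m <- sapply(c(age = "age", drift = "age-drift", ac = "age-cohort",
                apc = "apc", ap = "age-period"), dev_df)

  rows <- c("age", "drift", "ac", "apc", "ap", "drift")
  labels <- c("Age", "Age-drift", "Age-Cohort", "Age-Period-Cohort",
              "Age-Period", "Age-drift")
  dev <- m["dev", rows]
  df <- m["df", rows]
  p <- rep(NA_real_, 6)
  for (r in 2:4) p[r] <- lrt(dev[r - 1], df[r - 1], dev[r], df[r])
  # the last two comparisons run "backwards" up the nesting ladder:
  # Age-Period vs APC and Age-drift vs Age-Period
  p[5] <- lrt(dev[5], df[5], dev[4], df[4])
  p[6] <- lrt(dev[6], df[6], dev[5], df[5])

  tab <- data.frame(model = labels, df = as.integer(df),
                    deviance = unname(dev), p_value = unname(p))

  # smallest adequate model: each curvature is kept only if dropping it
  # from the full model loses fit at level alpha
  sig <- function(x) !is.na(x) && x <= alpha
  drift_sig <- sig(p[2])
  per_given_coh <- sig(p[4])   # APC vs Age-Cohort
  coh_given_per <- sig(p[5])   # APC vs Age-Period
  best <- if (per_given_coh && coh_given_per) "Age-Period-Cohort"
    else if (coh_given_per) "Age-Cohort"
    else if (per_given_coh) "Age-Period"
    else if (drift_sig) "Age-drift"
    else "Age"

  structure(tab, class = c("apc_model_table", "data.frame"),
            best_model = best, alpha = alpha,
            deviances = stats::setNames(m["dev", 1:5],
                                        c("Age", "Age-drift", "Age-Cohort",
                                          "Age-Period-Cohort", "Age-Period")))
}

#' @export
print.apc_model_table <- function(x, ...) {
  cat("Sequential deviance analysis of age-period-cohort sub-models\n")
  cat(sprintf("%-20s %5s %18s %12s\n", "Models", "Df", "Residual Deviance",
              "p (>|Chi|)"))
  for (r in seq_len(nrow(x))) {
    pv <- x$p_value[r]
    pv <- if (is.na(pv)) "" else if (pv < 1e-4) "<0.0001" else sprintf("%.4f", pv)
    cat(sprintf("%-20s %5d %18.2f %12s\n", x$model[r], x$df[r],
                x$deviance[r], pv))
  }
  cat("Best model (adjacent-line tests at ",
      attr(x, "alpha"), "): ", attr(x, "best_model"), "\n", sep = "")
  invisible(x)
}
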