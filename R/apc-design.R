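#' Cohort index on the Lexis lattice
#'
#' With ages indexed `i = 1..I` (youngest first) and periods `j = 1..J`
#' (earliest first), a synthetic (5-year) birth cohort is indexed
#' `k = j - i + I`, constant along Lexis diagonals.  There are
#' `K = I + J - 1` cohorts; `k = 1` is the oldest (largest age in the
#' earliest period) and `k = K` the youngest.
#'
#' @param i,j age and period indices (vectors recycle).
#' @param I number of age groups.
#' @return integer cohort index in `1..(I + J - 1)`.
#' @examples
#' cohort_index(13, 1, 13)  # oldest cohort
#' cohort_index(1, 8, 13)   # youngest of the 20
#' @export
cohort_index <- function(i, j, I) {
  if (any(i < 1L | i > I)) stop("age index i out of range 1..I")
  if (any(j < 1L)) stop("period index j must be >= 1")
  as.integer(j - i + I)
}

#' Age-period-cohort design
#'
#' Fixes the lattice geometry (age-group and period start years, cohort
#' labels), the reference period and cohort against which relative risks
#' are reported, and the parameterization mode.  Cohort start-year labels
#' are `period_start - age_start`, so a 13 x 8 grid starting at age 20 and
#' year 1980 spans cohorts 1900, 1905, ..., 1995.
#'
#' @param age_starts start years of the 5-year age groups (last open).
#' @param period_starts start years of the 5-year periods.
#' @param ref_period start year of the reference period (RR = 1); default
#'   1995 (the 1995-1999 quinquennium).
#' @param ref_cohort start year of the reference cohort; default 1945
#'   (the 1945-1949 birth cohort).
#' @param mode `"factor"` (one level per category, the default) or
#'   `"spline"` (natural cubic splines per time dimension).
#' @param spline_df named vector with elements `age`, `period`, `cohort`:
#'   basis dimensions used when `mode = "spline"`.
#' @return An object of class `apc_design`.
#' @export
apc_design <- function(age_starts = seq(20, 80, by = 5),
                       period_starts = seq(1980, 2015, by = 5),
                       ref_period = 1995,
                       ref_cohort = 1945,
                       mode = c("factor", "spline"),
                       spline_df = c(age = 8, period = 5, cohort = 6)) {
  mode <- match.arg(mode)
  I <- length(age_starts)
  J <- length(period_starts)
  K <- I + J - 1L
  cohort_starts <- min(period_starts) - rev(age_starts)[1] +
    5L * (seq_len(K) - 1L)
  stopifnot(max(cohort_starts) == max(period_starts) - min(age_starts))
  ref_j <- match(ref_period, period_starts)
  if (is.na(ref_j)) stop("ref_period is not a period start year of this design")
  ref_k <- match(ref_cohort, cohort_starts)
  if (is.na(ref_k)) stop("ref_cohort is not a cohort start year of this design")
  if (mode == "spline") {
    need <- c("age", "period", "cohort")
    if (!all(need %in% names(spline_df)))
      stop("spline_df must name age, period and cohort dimensions")
    spline_df <- spline_df[need]
  }
  structure(
    list(I = I, J = J, K = K,
         age_starts = as.integer(age_starts),
         period_starts = as.integer(period_starts),
         cohort_starts = as.integer(cohort_starts),
         ref_period = ref_period, ref_cohort = ref_cohort,
         ref_j = ref_j, ref_k = ref_k,
         mode = mode, spline_df = spline_df),
    class = "apc_design")
}

#' @export
print.apc_design <- function(x, ...) {
  cat(sprintf("<apc_design> I=%d ages, J=%d periods, K=%d cohorts (%d..%d); mode=%s\n",
              x$I, x$J, x$K, min(x$cohort_starts), max(x$cohort_starts), x$mode))
  cat(sprintf("  reference period %d-%d, reference cohort %d-%d\n",
              x$ref_period, x$ref_period + 4L, x$ref_cohort, x$ref_cohort + 4L))
  invisible(x)
}

# Orthonormal basis of the curvature space: all length-n vectors orthogonal
# to both the constant and the linear trend in the index.  Effects built
# from these columns have, by construction, zero mean and zero slope, so
# the model's single drift term carries the entire linear time trend.
curvature_basis <- function(n) {
  if (n < 3) return(matrix(numeric(0), nrow = n, ncol = 0))
  X <- cbind(1, seq_len(n))
  Q <- qr.Q(qr(X), complete = TRUE)
  B <- Q[, -(1:2), drop = FALSE]
  colnames(B) <- paste0("c", seq_len(ncol(B)))
  B
}

# Spline variant: natural-spline columns in the index, projected off the
# constant + linear span, then reduced to a full-rank set.
spline_curvature_basis <- function(n, df) {
  df <- as.integer(df)
  if (df < 3 || n < 3) return(matrix(numeric(0), nrow = n, ncol = 0))
  S <- splines::ns(seq_len(n), df = min(df, n - 1L))
  X <- cbind(1, seq_len(n))
  P <- diag(n) - X %*% solve(crossprod(X), t(X))
  R <- P %*% S
  q <- qr(R)
  B <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  colnames(B) <- paste0("c", seq_len(ncol(B)))
  B
}

# Cell-level covariates for a grid under a design: long data frame with
# one row per Lexis cell, in column-major (period-fastest last) order.
apc_frame <- function(grid, design) {
  I <- design$I; J <- design$J
  if (nrow(grid$D) != I || ncol(grid$D) != J)
    stop("grid dimensions do not match the design")
  if (!all(grid$age_starts == design$age_starts) ||
      !all(grid$period_starts == design$period_starts))
    stop("grid age/period labels do not match the design")
  i <- rep(seq_len(I), times = J)
  j <- rep(seq_len(J), each = I)
  data.frame(i = i, j = j, k = cohort_index(i, j, I),
             D = as.vector(grid$D), N = as.vector(grid$N))
}

# Model matrix for one of the five nested sub-models.  All time trend is
# carried by a single "drift" column (period index centred at the
# reference period, units of one 5-year step); period and cohort enter
# only through slope-free curvature columns, which makes every sub-model
# nested in the next and the APC fit identifiable.
apc_model_matrix <- function(design, model = c("apc", "age", "age-drift",
                                               "age-period", "age-cohort"),
                             frame) {
  model <- match.arg(model)
  I <- design$I; J <- design$J; K <- design$K
  if (design$mode == "factor") {
    Ba <- cbind(1, stats::contr.treatment(I))
    colnames(Ba) <- c("(Intercept)", paste0("age", 2:I))
  } else {
    dfa <- min(design$spline_df[["age"]], I - 1L)
    Ba <- cbind(1, splines::ns(seq_len(I), df = dfa))
    colnames(Ba) <- c("(Intercept)", paste0("age.s", seq_len(ncol(Ba) - 1L)))
  }
  A <- Ba[frame$i, , drop = FALSE]
  drift <- frame$j - design$ref_j
  Bp <- if (design$mode == "factor") curvature_basis(J) else
    spline_curvature_basis(J, design$spline_df[["period"]])
  Bk <- if (design$mode == "factor") curvature_basis(K) else
    spline_curvature_basis(K, design$spline_df[["cohort"]])
  Xp <- Bp[frame$j, , drop = FALSE]
  Xk <- Bk[frame$k, , drop = FALSE]
  if (ncol(Xp)) colnames(Xp) <- paste0("per.", colnames(Bp))
  if (ncol(Xk)) colnames(Xk) <- paste0("coh.", colnames(Bk))
  X <- switch(model,
    "age"        = A,
    "age-drift"  = cbind(A, drift = drift),
    "age-period" = cbind(A, drift = drift, Xp),
    "age-cohort" = cbind(A, drift = drift, Xk),
    "apc"        = cbind(A, drift = drift, Xp, Xk))
  attr(X, "age_basis") <- Ba
  attr(X, "period_basis") <- Bp
  attr(X, "cohort_basis") <- Bk
  X
}
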