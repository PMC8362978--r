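#' Mortality grid: deaths and person-years on an age x period lattice
#'
#' The central data container: an `I x J` matrix of death counts `D` (raw
#' integers or real-valued corrected counts) and a matching matrix of
#' person-years at risk `N`, indexed by 5-year age groups (rows, youngest
#' first) and 5-year calendar periods (columns, earliest first).  The last
#' age group is open (e.g. 80+).
#'
#' @param D numeric `I x J` matrix of deaths; non-negative, may be
#'   real-valued (corrected counts).
#' @param N numeric `I x J` matrix of person-years; strictly positive.
#' @param age_starts integer vector of length `I`: start year of each 5-year
#'   age group (default 20, 25, ..., 80 with 80 meaning 80+).
#' @param period_starts integer vector of length `J`: start calendar year of
#'   each 5-year period (default 1980, 1985, ..., 2015).
#' @param unit label of the geographic unit the grid belongs to.
#' @return An object of class `mortality_grid`.
#' @examples
#' g <- mortality_grid(matrix(5, 13, 8), matrix(1e5, 13, 8))
#' dim(g$D)
#' @export
mortality_grid <- function(D, N,
                           age_starts = seq(20, by = 5, length.out = nrow(D)),
                           period_starts = seq(1980, by = 5, length.out = ncol(D)),
                           unit = "unit") {
  D <- as.matrix(D)
  N <- as.matrix(N)
  if (!all(dim(D) == dim(N)))
    stop("D and N must have identical dimensions")
  if (length(age_starts) != nrow(D))
    stop("age_starts must have one entry per row of D")
  if (length(period_starts) != ncol(D))
    stop("period_starts must have one entry per column of D")
  if (any(!is.finite(D)) || any(D < 0))
    stop("deaths must be finite and non-negative")
  if (any(!is.finite(N)) || any(N <= 0))
    stop("person-years must be finite and strictly positive")
  if (is.unsorted(age_starts, strictly = TRUE) ||
      is.unsorted(period_starts, strictly = TRUE))
    stop("age_starts and period_starts must be strictly increasing")
  dimnames(D) <- dimnames(N) <- list(age = age_starts, period = period_starts)
  structure(
    list(D = D, N = N,
         age_starts = as.integer(age_starts),
         period_starts = as.integer(period_starts),
         unit = unit),
    class = "mortality_grid")
}

#' @export
print.mortality_grid <- function(x, ...) {
  cat(sprintf("<mortality_grid> unit '%s': %d age groups (%d-%d+) x %d periods (%d-%d)\n",
              x$unit, nrow(x$D), min(x$age_starts), max(x$age_starts),
              ncol(x$D), min(x$period_starts), max(x$period_starts) + 4L))
  cat(sprintf("  total deaths %.1f, total person-years %.4g\n",
              sum(x$D), sum(x$N)))
  invisible(x)
}

#' @export
dim.mortality_grid <- function(x) dim(x$D)

is_mortality_grid <- function(x) inherits(x, "mortality_grid")
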