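#' Age-specific mortality rates
#'
#' @param grid a [mortality_grid()].
#' @param scale rate denominator (default per 100,000 person-years).
#' @return `I x J` matrix of rates.
#' @export
age_specific_rates <- function(grid, scale = 1e5) {
  stopifnot(is_mortality_grid(grid))
  scale * grid$D / grid$N
}

#' Crude (all-ages) mortality rate per period
#'
#' @inheritParams age_specific_rates
#' @return named vector, one rate per period.
#' @export
crude_rate <- function(grid, scale = 1e5) {
  stopifnot(is_mortality_grid(grid))
  stats::setNames(scale * colSums(grid$D) / colSums(grid$N),
                  grid$period_starts)
}

#' Truncated mortality rate from an age floor upward
#'
#' Pools deaths and person-years over all age groups at or above
#' `age_floor` (e.g. the open 80+ interval), per period.
#'
#' @inheritParams age_specific_rates
#' @param age_floor a start year among the grid's age groups.
#' @return named vector, one rate per period.
#' @export
truncated_rate <- function(grid, age_floor, scale = 1e5) {
  stopifnot(is_mortality_grid(grid))
  if (!age_floor %in% grid$age_starts)
    stop("age_floor must be one of the grid's age group start years")
  sel <- grid$age_starts >= age_floor
  stats::setNames(
    scale * colSums(grid$D[sel, , drop = FALSE]) /
      colSums(grid$N[sel, , drop = FALSE]),
    grid$period_starts)
}

#' Segi world standard population (Doll-Hill modification), ages 20+
#'
#' The packaged standard weights used for direct standardization,
#' restricted to the analysis ages (20-24 through the open 80+ group,
#' whose weight pools the 80-84 and 85+ classes).
#'
#' @return data frame with columns `age_start` and `weight`.
#' @export
segi_standard <- function() {
  path <- system.file("extdata", "segi_world_20plus.csv",
                      package = "apcmort", mustWork = TRUE)
  read_standard_population(path)
}

#' Read a standard population table
#'
#' @param path CSV with columns `age_start` and `weight`.
#' @return validated data frame.
#' @export
read_standard_population <- function(path) {
  std <- utils::read.csv(path)
  if (!all(c("age_start", "weight") %in% names(std)))
    stop("standard population needs columns age_start and weight")
  if (any(std$weight < 0) || all(std$weight == 0))
    stop("standard weights must be non-negative with at least one positive")
  std[c("age_start", "weight")]
}

#' Directly standardized rate
#'
#' Weighted average of age-specific rates with fixed standard-population
#' weights: `sum(w_i r_i) / sum(w_i)`.
#'
#' @param age_rates length-`I` vector of age-specific rates, or an
#'   `I x J` matrix (one standardized rate per period is returned).
#' @param std a standard population: data frame from
#'   [read_standard_population()]/[segi_standard()] or a plain numeric
#'   weight vector of length `I`.
#' @return a single rate, or a vector of rates for matrix input.
#' @examples
#' direct_standardized_rate(c(10, 20), c(8000, 2000))
#' @export
direct_standardized_rate <- function(age_rates, std = segi_standard()) {
  w <- if (is.data.frame(std)) std$weight else as.numeric(std)
  if (all(w == 0)) stop("standard weights are all zero")
  if (is.matrix(age_rates)) {
    if (nrow(age_rates) != length(w))
      stop("weights and age groups do not align")
    return(drop(crossprod(w, age_rates)) / sum(w))
  }
  if (length(age_rates) != length(w))
    stop("weights and age groups do not align")
  sum(w * age_rates) / sum(w)
}

#' Percent change between two rates
#'
#' `100 * (last - first) / first`; the conventional summary for comparing
#' the last quinquennium with the first.
#'
#' @param first,last rates; `first` must be positive.
#' @return percent change.
#' @examples
#' percent_change(12.31, 19.95)
#' @export
percent_change <- function(first, last) {
  if (any(first <= 0)) stop("the baseline rate must be positive")
  100 * (last - first) / first
}

#' Period-average of standardized rates
#'
#' Published period summaries can be simple means of the quinquennial
#' standardized rates or person-year-weighted means; both are provided.
#'
#' @param rates vector of per-period rates.
#' @param person_years optional per-period person-years for the weighted
#'   variant.
#' @param weights `"equal"` (default) or `"person_years"`.
#' @return the average rate.
#' @export
mean_period_rate <- function(rates, person_years = NULL,
                             weights = c("equal", "person_years")) {
  weights <- match.arg(weights)
  if (weights == "equal") return(mean(rates))
  if (is.null(person_years))
    stop("person_years needed for the person-year-weighted mean")
  sum(rates * person_years) / sum(person_years)
}

#' Published standardized breast-cancer mortality rates, Brazilian
#' Northeast states, 1980-2019
#'
#' Packaged table of directly standardized rates (per 100,000 women) by
#' state and quinquennium at three correction stages: uncorrected (UMR),
#' after cause redistribution (CMR), and fully corrected including
#' under-registration (CMRQIUD).
#'
#' @return data frame with columns `locality`, `correction`,
#'   `period_start`, `rate`.
#' @export
published_rate_table <- function() {
  path <- system.file("extdata", "ne_standardized_rates.csv",
                      package = "apcmort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Percent increase first-to-last period from a published rate table
#'
#' @param tab a table in the [published_rate_table()] layout.
#' @param correction which correction stage to summarize (default the
#'   fully corrected rates).
#' @param exclude localities to leave out (default the regional
#'   aggregate, keeping the nine states).
#' @return data frame with columns `locality`, `first`, `last`,
#'   `pct_change`.
#' @export
rate_table_percent_increase <- function(tab = published_rate_table(),
                                        correction = "CMRQIUD",
                                        exclude = "Northeast") {
  tab <- tab[tab$correction == correction & !tab$locality %in% exclude, ]
  out <- do.call(rbind, lapply(split(tab, tab$locality), function(d) {
    d <- d[order(d$period_start), ]
    data.frame(locality = d$locality[1],
               first = d$rate[1], last = d$rate[nrow(d)],
               pct_change = percent_change(d$rate[1], d$rate[nrow(d)]))
  }))
  rownames(out) <- NULL
  out
}
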