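# run code under a temporary RNG state so generation never disturbs (or
# depends on) the caller's random stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# default Lexis-surface effects: a steep log-linear rise of breast-cancer
# mortality with age that flattens at old ages, a mild period curvature,
# and cohort effects carrying most of the secular increase
default_age_effects <- function(I) {
  x <- seq(0, 1, length.out = I)
  6.3 * x - 1.0 * x^2 - 3.4
}
default_period_effects <- function(J) {
  x <- seq_len(J) - (J + 1) / 2
  0.03 * x - 0.01 * x^2 + 0.01 * mean(x^2)
}
default_cohort_effects <- function(K) {
  x <- seq_len(K)
  0.05 * (x - 10) + 0.004 * pmax(0, x - 12)^2
}

#' Configuration of the synthetic mortality registry
#'
#' Defines the generating truth (a log-linear age + period + cohort
#' Lexis surface) and the data-quality corruption of a simulated
#' registry: miscoding of cancer deaths to incomplete diagnoses,
#' miscoding of natural deaths to the ill-defined chapter, and
#' decade-dependent under-registration.
#'
#' @param n_age_groups number of 5-year age groups `I` (default 13,
#'   ages 20-24 through 80+).
#' @param n_periods number of 5-year periods `J` (default 8, 1980-1984
#'   through 2015-2019).
#' @param first_age,first_period_start start of the first age group and
#'   first period.
#' @param population_base person-years at risk per Lexis cell (default
#'   1e6, roughly a mid-sized state's female 5-year age group observed
#'   over a 5-year period).
#' @param mu baseline log mortality rate (per person-year); default -9,
#'   about 12 deaths per 100,000 person-years before effects.
#' @param age_effects,period_effects,cohort_effects log-scale effect
#'   vectors of lengths `I`, `J` and `K = I + J - 1`.
#' @param p_ill_defined probability a natural death is coded ill-defined.
#' @param p_incomplete probability a cancer death is coded as an
#'   incomplete/unspecified cancer diagnosis.
#' @param completeness named vector, decade start year to probability the
#'   death is registered at all, values in (0, 1].
#' @param frac_other_cancer,frac_other_natural,frac_non_natural cause-mix
#'   multipliers: expected deaths from other specified cancers / other
#'   natural causes / external causes per expected breast-cancer death in
#'   the same cell.
#' @param unit label given to the simulated geographic unit.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_age_groups = 13L,
                             n_periods = 8L,
                             first_age = 20L,
                             first_period_start = 1980L,
                             population_base = 1e6,
                             mu = -9,
                             age_effects = default_age_effects(n_age_groups),
                             period_effects = default_period_effects(n_periods),
                             cohort_effects = default_cohort_effects(n_age_groups + n_periods - 1L),
                             p_ill_defined = 0.10,
                             p_incomplete = 0.08,
                             completeness = c("1980" = 0.80, "1990" = 0.85,
                                              "2000" = 0.92, "2010" = 0.97),
                             frac_other_cancer = 2,
                             frac_other_natural = 15,
                             frac_non_natural = 2,
                             unit = "SYN",
                             seed = NULL) {
  I <- as.integer(n_age_groups); J <- as.integer(n_periods)
  K <- I + J - 1L
  # YAML 1.1 reads plain "3.0e5" as a string; be lenient with config input
  population_base <- as.numeric(population_base)
  if (length(age_effects) != I)
    stop("age_effects must have length ", I)
  if (length(period_effects) != J)
    stop("period_effects must have length ", J)
  if (length(cohort_effects) != K)
    stop("cohort_effects must have length K = I + J - 1 = ", K)
  if (population_base <= 0) stop("population_base must be positive")
  probs <- c(p_ill_defined = p_ill_defined, p_incomplete = p_incomplete)
  if (any(probs < 0 | probs > 1))
    stop("corruption probabilities must lie in [0, 1]")
  if (any(completeness <= 0 | completeness > 1))
    stop("completeness values must lie in (0, 1]")
  if (is.null(names(completeness)))
    stop("completeness must be named by decade start year")
  fracs <- c(frac_other_cancer, frac_other_natural, frac_non_natural)
  if (any(fracs < 0)) stop("cause-mix fractions must be non-negative")
  structure(
    list(I = I, J = J, K = K,
         age_starts = seq(first_age, by = 5L, length.out = I),
         period_starts = seq(first_period_start, by = 5L, length.out = J),
         population_base = population_base, mu = mu,
         age_effects = age_effects, period_effects = period_effects,
         cohort_effects = cohort_effects,
         p_ill_defined = p_ill_defined, p_incomplete = p_incomplete,
         completeness = completeness,
         frac_other_cancer = frac_other_cancer,
         frac_other_natural = frac_other_natural,
         frac_non_natural = frac_non_natural,
         unit = unit, seed = seed),
    class = "synthetic_config")
}

#' True breast-cancer rate surface of a synthetic configuration
#'
#' `rate[i, j] = exp(mu + age[i] + period[j] + cohort[k(i, j)])` with
#' `k(i, j) = j - i + I` — the generating Lexis surface, per person-year.
#'
#' @param config a [synthetic_config()].
#' @return strictly positive `I x J` matrix of rates.
#' @export
generate_true_rates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  I <- config$I; J <- config$J
  i <- rep(seq_len(I), times = J)
  j <- rep(seq_len(J), each = I)
  k <- cohort_index(i, j, I)
  r <- exp(config$mu + config$age_effects[i] + config$period_effects[j] +
             config$cohort_effects[k])
  matrix(r, I, J, dimnames = list(age = config$age_starts,
                                  period = config$period_starts))
}

#' Sample a death-count grid from the generating surface
#'
#' Draws `D[i, j] ~ Poisson(population_base * rate[i, j])` — the clean
#' (uncorrupted, fully registered) breast-cancer death grid.
#'
#' @param config a [synthetic_config()].
#' @return a [mortality_grid()].
#' @export
synthetic_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rate <- generate_true_rates(config)
  D <- with_seed(config$seed,
                 matrix(stats::rpois(length(rate), config$population_base * rate),
                        nrow(rate), ncol(rate)))
  mortality_grid(D, matrix(config$population_base, nrow(rate), ncol(rate)),
                 config$age_starts, config$period_starts, unit = config$unit)
}

# code pools per cause class and ICD revision
.icd_pool <- function(class, rev) {
  if (rev == 9L) switch(class,
    BREAST = "174",
    OTHER_DEFINED_CANCER = c("151", "162", "180", "183"),
    INCOMPLETE_CANCER = c("195", "196", "197", "198", "199"),
    ILL_DEFINED = c("780", "785", "797", "799"),
    OTHER_DEFINED_NATURAL = c("250", "410", "486", "571"),
    NON_NATURAL = c("E810", "E880", "960"))
  else switch(class,
    BREAST = "C50",
    OTHER_DEFINED_CANCER = c("C16", "C34", "C53", "C56"),
    INCOMPLETE_CANCER = ICD10_INCOMPLETE,
    ILL_DEFINED = c("R00", "R54", "R98", "R99"),
    OTHER_DEFINED_NATURAL = c("E14", "I21", "J18", "K74"),
    NON_NATURAL = c("V89", "W19", "X70", "Y09"))
}

#' Generate registry-like death records with known ground truth
#'
#' Per Lexis cell, breast-cancer deaths are drawn from a Poisson law with
#' mean `N_ij * rate_ij`; other specified cancers, other natural causes
#' and external causes are added with Poisson means scaled by the
#' cause-mix fractions.  Corruption is then applied in registry order:
#' each cancer death is recoded to an incomplete-diagnosis code with
#' probability `p_incomplete`, each natural death (including recoded
#' ones) to an ill-defined code with probability `p_ill_defined`, and
#' finally each death is dropped — never registered — with probability
#' `1 - completeness(decade)`.  External-cause deaths are never recoded.
#'
#' @param config a [synthetic_config()].
#' @param resolution `"period"` (default: deaths dated at the period start
#'   year, the analysis resolution) or `"year"` (uniform disaggregation
#'   over the 5 calendar years of the period).
#' @return list of class `synthetic_registry` with elements
#'   `true_rate_grid`, `true_death_grid` (expected breast deaths),
#'   `breast_sampled` (the realized clean breast grid), `records` (data
#'   frame: year, age_years, icd_revision, icd_code, sex, unit),
#'   `dropped_count`, and `config`.
#' @export
generate_records <- function(config, resolution = c("period", "year")) {
  stopifnot(inherits(config, "synthetic_config"))
  resolution <- match.arg(resolution)
  rate <- generate_true_rates(config)
  I <- config$I; J <- config$J
  N <- config$population_base

  with_seed(config$seed, {
    mix <- c(BREAST = 1,
             OTHER_DEFINED_CANCER = config$frac_other_cancer,
             OTHER_DEFINED_NATURAL = config$frac_other_natural,
             NON_NATURAL = config$frac_non_natural)
    counts <- lapply(names(mix), function(cl)
      matrix(stats::rpois(I * J, N * rate * mix[[cl]]), I, J))
    names(counts) <- names(mix)

    cell <- expand.grid(i = seq_len(I), j = seq_len(J))
    rec <- do.call(rbind, lapply(names(counts), function(cl) {
      n <- as.vector(counts[[cl]])
      data.frame(i = rep(cell$i, n), j = rep(cell$j, n),
                 true_class = cl, stringsAsFactors = FALSE)
    }))
    rec$age_years <- config$age_starts[rec$i]
    rec$year <- config$period_starts[rec$j]
    if (resolution == "year")
      rec$year <- rec$year + sample(0:4, nrow(rec), replace = TRUE)

    # corruption stage 1: cancers miscoded as incomplete diagnosis
    coded <- rec$true_class
    is_cancer <- coded %in% c("BREAST", "OTHER_DEFINED_CANCER")
    flip <- is_cancer & stats::runif(nrow(rec)) < config$p_incomplete
    coded[flip] <- "INCOMPLETE_CANCER"
    # stage 2: natural deaths miscoded as ill-defined
    is_natural <- coded != "NON_NATURAL"
    flip <- is_natural & stats::runif(nrow(rec)) < config$p_ill_defined
    coded[flip] <- "ILL_DEFINED"
    rec$coded_class <- coded

    # stage 3: under-registration by decade
    comp <- config$completeness[as.character(decade_of(rec$year))]
    if (any(is.na(comp)))
      stop("completeness is missing a decade touched by the data")
    registered <- stats::runif(nrow(rec)) < comp
    dropped <- sum(!registered)
    rec <- rec[registered, , drop = FALSE]

    rec$icd_revision <- ifelse(rec$year < 1996L, 9L, 10L)
    rec$icd_code <- NA_character_
    for (cl in unique(rec$coded_class)) {
      for (rv in c(9L, 10L)) {
        idx <- which(rec$coded_class == cl & rec$icd_revision == rv)
        if (length(idx)) {
          pool <- .icd_pool(cl, rv)
          rec$icd_code[idx] <- pool[sample.int(length(pool), length(idx),
                                               replace = TRUE)]
        }
      }
    }
    rec$sex <- "F"
    rec$unit <- config$unit
    rownames(rec) <- NULL

    structure(
      list(true_rate_grid = rate,
           true_death_grid = N * rate,
           breast_sampled = counts$BREAST,
           records = rec[c("year", "age_years", "icd_revision", "icd_code",
                           "sex", "unit")],
           records_full = rec,
           dropped_count = dropped,
           config = config),
      class = "synthetic_registry")
  })
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat(sprintf("<synthetic_registry> unit '%s': %d registered deaths (%d dropped)\n",
              x$config$unit, nrow(x$records), x$dropped_count))
  cat(sprintf("  true breast deaths expected %.1f, sampled %d\n",
              sum(x$true_death_grid), sum(x$breast_sampled)))
  invisible(x)
}

#' Expected registered (pre-correction) breast-cancer count
#'
#' Analytic expectation of the breast-coded registered deaths per cell
#' under the configured corruption: the Poisson mean thinned by the
#' incomplete-coding, ill-defined-coding and registration probabilities.
#' Used as an oracle for corruption-monotonicity checks.
#'
#' @param config a [synthetic_config()].
#' @return `I x J` matrix of expected registered breast-coded deaths.
#' @export
expected_registered_breast <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  rate <- generate_true_rates(config)
  comp <- config$completeness[as.character(decade_of(config$period_starts))]
  keep <- (1 - config$p_incomplete) * (1 - config$p_ill_defined)
  sweep(config$population_base * rate * keep, 2, comp, "*")
}
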