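#' Tabulate death records by Lexis cell and cause class
#'
#' Classifies each record with [classify_cause()] and counts deaths by
#' geographic unit, 5-year period, 5-year age group and cause class.
#' Records younger than the first age group or outside the period range
#' are dropped (the analysis restricts to women aged 20+ within the study
#' window).
#'
#' @param records data frame with columns `year`, `age_years`,
#'   `icd_revision`, `icd_code` and optionally `unit` (default `"unit"`).
#' @param age_starts,period_starts 5-year bin start years (left-closed);
#'   the last age group is open-ended.
#' @return A wide data frame of class `cause_tabulation`: one row per
#'   (unit, period_start, age_start) cell, one count column per cause
#'   class, every cell of the lattice present.
#' @export
tabulate_causes <- function(records,
                            age_starts = seq(20, 80, by = 5),
                            period_starts = seq(1980, 2015, by = 5)) {
  need <- c("year", "age_years", "icd_revision", "icd_code")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  unit <- if ("unit" %in% names(records)) records$unit else "unit"
  keep <- records$age_years >= min(age_starts) &
    records$year >= min(period_starts) &
    records$year <= max(period_starts) + 4L
  records <- records[keep, , drop = FALSE]
  unit <- rep_len(unit, nrow(records))
  cls <- classify_cause(records$icd_code, records$icd_revision)
  age_bin <- age_starts[findInterval(records$age_years, age_starts)]
  per_bin <- period_starts[findInterval(records$year, period_starts)]
  tab <- as.data.frame(table(
    unit = factor(unit),
    period_start = factor(per_bin, levels = period_starts),
    age_start = factor(age_bin, levels = age_starts),
    cause_class = factor(cls, levels = CAUSE_CLASSES)))
  wide <- stats::reshape(tab, idvar = c("unit", "period_start", "age_start"),
                         timevar = "cause_class", direction = "wide")
  names(wide) <- sub("^Freq\\.", "", names(wide))
  wide$period_start <- as.integer(as.character(wide$period_start))
  wide$age_start <- as.integer(as.character(wide$age_start))
  wide$unit <- as.character(wide$unit)
  wide <- wide[order(wide$unit, wide$period_start, wide$age_start), ]
  rownames(wide) <- NULL
  for (cc in setdiff(CAUSE_CLASSES, names(wide))) wide[[cc]] <- 0
  as_cause_tabulation(wide[c("unit", "period_start", "age_start", CAUSE_CLASSES)])
}

#' Construct a cause tabulation from pre-aggregated counts
#'
#' @param df data frame with columns `unit`, `period_start`, `age_start`
#'   and one non-negative count column per [CAUSE_CLASSES] entry (missing
#'   class columns are filled with zero).
#' @return The validated data frame with class `cause_tabulation`.
#' @export
as_cause_tabulation <- function(df) {
  need <- c("unit", "period_start", "age_start")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("tabulation is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in setdiff(CAUSE_CLASSES, names(df))) df[[cc]] <- 0
  counts <- as.matrix(df[CAUSE_CLASSES])
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("cause counts must be finite and non-negative")
  structure(df[c(need, CAUSE_CLASSES)], class = c("cause_tabulation", "data.frame"))
}

# stratum keys for proportional redistribution
.strata_key <- function(tab, strata) {
  switch(strata,
         unit_period_age = interaction(tab$unit, tab$period_start,
                                       tab$age_start, drop = FALSE),
         unit = factor(tab$unit),
         stop("unknown strata mode: ", strata))
}

#' Partially redistribute ill-defined deaths among defined natural causes
#'
#' Step (i) of the correction: within each redistribution stratum, a
#' `fraction` (default 0.5, i.e. 50%) of deaths coded to the ill-defined
#' chapter is redistributed proportionally over the defined natural
#' classes (breast, other specified cancer, other specified natural);
#' external causes never receive redistributed deaths.  The grand total of
#' deaths is conserved.  Strata holding ill-defined deaths but no defined
#' natural deaths are left untouched with a warning.
#'
#' @param tab a `cause_tabulation`.
#' @param fraction share of ill-defined deaths to redistribute, in [0,1].
#' @param strata `"unit_period_age"` (default: redistribute within each
#'   Lexis cell, preserving the age/period surface) or `"unit"` (pool the
#'   proportional shares over the whole unit).
#' @return The tabulation with real-valued counts after redistribution.
#' @export
redistribute_ill_defined <- function(tab, fraction = 0.5,
                                     strata = c("unit_period_age", "unit")) {
  stopifnot(inherits(tab, "cause_tabulation"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  strata <- match.arg(strata)
  target <- c("BREAST", "OTHER_DEFINED_CANCER", "OTHER_DEFINED_NATURAL")
  key <- .strata_key(tab, strata)
  denom_by <- rowsum(rowSums(tab[target]), key)[, 1]
  moved <- fraction * tab$ILL_DEFINED
  denom <- denom_by[as.character(key)]
  stuck <- moved > 0 & denom == 0
  if (any(stuck)) {
    warning(sum(tab$ILL_DEFINED[stuck]),
            " ill-defined death(s) left in place: no defined natural deaths ",
            "in their stratum")
    moved[stuck] <- 0
  }
  for (cc in target) {
    share_by <- rowsum(tab[[cc]], key)[, 1] / ifelse(denom_by > 0, denom_by, 1)
    tab[[cc]] <- tab[[cc]] + moved * share_by[as.character(key)]
  }
  tab$ILL_DEFINED <- tab$ILL_DEFINED - moved
  tab
}

#' Redistribute incomplete cancer diagnoses among specified cancers
#'
#' Step (ii) of the correction: within each (unit, period, age group)
#' stratum, deaths coded to unspecified/secondary malignant sites are
#' fully redistributed proportionally over the specified cancer classes
#' (breast, other specified cancer).  Totals are conserved; strata with
#' incomplete deaths but no specified cancer deaths are left untouched
#' with a warning.
#'
#' @param tab a `cause_tabulation`.
#' @return The tabulation with real-valued counts after redistribution.
#' @export
redistribute_incomplete_cancer <- function(tab) {
  stopifnot(inherits(tab, "cause_tabulation"))
  target <- c("BREAST", "OTHER_DEFINED_CANCER")
  denom <- rowSums(tab[target])
  moved <- tab$INCOMPLETE_CANCER
  stuck <- moved > 0 & denom == 0
  if (any(stuck)) {
    warning(sum(moved[stuck]),
            " incomplete-cancer death(s) left in place: no specified cancer ",
            "deaths in their stratum")
    moved[stuck] <- 0
  }
  safe <- ifelse(denom > 0, denom, 1)
  for (cc in target)
    tab[[cc]] <- tab[[cc]] + moved * tab[[cc]] / safe
  tab$INCOMPLETE_CANCER <- tab$INCOMPLETE_CANCER - moved
  tab
}

#' Decade-specific completeness correction factors
#'
#' @param factors named numeric vector (names are decade start years, e.g.
#'   `c("1980" = 1.25, "1990" = 1.18, ...)`) or a data frame with columns
#'   `decade` and `factor` (and optionally `unit`).  Factors must be
#'   finite and at least 1 (they are inverse registration completeness).
#' @return data frame of class `correction_factors` with columns `unit`,
#'   `decade`, `factor` (`unit = "*"` applies to every unit).
#' @export
correction_factors <- function(factors) {
  if (is.numeric(factors) && !is.null(names(factors))) {
    factors <- data.frame(unit = "*",
                          decade = as.integer(names(factors)),
                          factor = unname(factors))
  }
  need <- c("decade", "factor")
  if (!all(need %in% names(factors)))
    stop("factors need a decade and a factor column (or a named vector)")
  if (!"unit" %in% names(factors)) factors$unit <- "*"
  if (any(!is.finite(factors$factor)) || any(factors$factor < 1))
    stop("completeness factors must be finite and >= 1")
  structure(factors[c("unit", "decade", "factor")],
            class = c("correction_factors", "data.frame"))
}

.lookup_factor <- function(factors, unit, year) {
  dec <- decade_of(year)
  out <- numeric(length(year))
  unit <- rep_len(unit, length(year))
  for (idx in seq_along(year)) {
    hit <- factors$decade == dec[idx] &
      (factors$unit == unit[idx] | factors$unit == "*")
    if (!any(hit))
      stop("no completeness factor for unit '", unit[idx],
           "', decade ", dec[idx])
    out[idx] <- factors$factor[which(hit)[1]]
  }
  out
}

#' Apply completeness (under-registration) factors
#'
#' Step (iv): multiplies counts by the decade-specific completeness factor
#' of the decade their year (or period start) falls in.  Counts stay
#' real-valued; nothing is rounded.
#'
#' @param counts numeric vector of death counts.
#' @param years calendar year (or period start year) per count.
#' @param factors a [correction_factors()] table.
#' @param unit geographic unit per count (default `"*"`).
#' @return numeric vector of corrected counts.
#' @examples
#' apply_completeness(40, 1987, correction_factors(c("1980" = 1.25)))
#' @export
apply_completeness <- function(counts, years, factors, unit = "*") {
  factors <- correction_factors(factors)
  if (length(years) != length(counts))
    years <- rep_len(years, length(counts))
  counts * .lookup_factor(factors, unit, years)
}

#' Four-step correction of registered breast-cancer deaths
#'
#' Composes the full correction: (i) proportional redistribution of 50%
#' (configurable) of ill-defined deaths among defined natural causes;
#' (ii) proportional redistribution of incomplete cancer diagnoses among
#' specified cancers; (iii) the breast-cancer shares from both steps are
#' added to the registered breast-cancer deaths; (iv) the sum is
#' multiplied by the decade-specific completeness factor.  The shares in
#' steps (i) and (ii) are both computed from the original registered
#' tabulation (parallel, not sequential, composition).
#'
#' @param x death records (data frame, see [tabulate_causes()]) or a
#'   pre-aggregated `cause_tabulation` — both paths give identical output.
#' @param factors a [correction_factors()] table (use factors of 1 for no
#'   coverage correction).
#' @param person_years optional `I x J` matrix of person-years; when
#'   supplied the result is a [mortality_grid()] whose `D` holds the
#'   corrected counts (the raw registered breast counts are kept in the
#'   `"D_raw"` attribute), otherwise a list with matrices `D_raw` and
#'   `D_corrected`.
#' @param age_starts,period_starts lattice definition.
#' @param fraction ill-defined redistribution share (default 0.5).
#' @param ill_defined_strata stratification for step (i); see
#'   [redistribute_ill_defined()].
#' @return See `person_years`.
#' @export
correct_pipeline <- function(x, factors,
                             person_years = NULL,
                             age_starts = seq(20, 80, by = 5),
                             period_starts = seq(1980, 2015, by = 5),
                             fraction = 0.5,
                             ill_defined_strata = "unit_period_age") {
  tab <- if (inherits(x, "cause_tabulation")) x else
    tabulate_causes(x, age_starts, period_starts)
  if (length(unique(tab$unit)) != 1)
    stop("correct_pipeline expects a single geographic unit per call")
  tab <- tab[order(tab$period_start, tab$age_start), ]
  cells <- expand.grid(age_start = age_starts, period_start = period_starts)
  if (nrow(tab) != nrow(cells) ||
      !all(tab$age_start == cells$age_start) ||
      !all(tab$period_start == cells$period_start))
    stop("tabulation does not cover the full age x period lattice")
  factors <- correction_factors(factors)

  raw_breast <- tab$BREAST
  gain_ill <- redistribute_ill_defined(tab, fraction,
                                       ill_defined_strata)$BREAST - raw_breast
  gain_inc <- redistribute_incomplete_cancer(tab)$BREAST - raw_breast
  summed <- raw_breast + gain_ill + gain_inc
  corrected <- apply_completeness(summed, tab$period_start, factors,
                                  unit = tab$unit)

  # tab rows are sorted period-major, age within period: column-major fill
  shape <- function(v) matrix(as.numeric(v), nrow = length(age_starts),
                              dimnames = list(age = age_starts,
                                              period = period_starts))
  D_raw <- shape(raw_breast)
  D_corr <- shape(corrected)
  if (is.null(person_years))
    return(list(D_raw = D_raw, D_corrected = D_corr,
                age_starts = age_starts, period_starts = period_starts,
                unit = tab$unit[1]))
  g <- mortality_grid(D_corr, person_years, age_starts, period_starts,
                      unit = tab$unit[1])
  attr(g, "D_raw") <- D_raw
  g
}
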