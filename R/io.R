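# All tables are plain CSV with explicit headers; numbers are written with
# 15 significant digits so a write/read round trip is lossless to 12.
.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a record-level death table or a pre-aggregated cause tabulation
#'
#' Record CSVs carry columns `year`, `age_years`, `icd_revision`,
#' `icd_code` (plus optional `unit`, `sex`); aggregated CSVs carry `unit`,
#' `period_start`, `age_start` and one column per cause class.  Malformed
#' rows are rejected with their line numbers.
#'
#' @param path CSV file.
#' @return a records data frame, or a `cause_tabulation` for aggregated
#'   input.
#' @export
read_death_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("unit", "period_start", "age_start") %in% names(df)))
    return(as_cause_tabulation(df))
  need <- c("year", "age_years", "icd_revision", "icd_code")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("death table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df)
  bad <- which(!is.finite(df$year) | !is.finite(df$age_years) |
                 df$age_years < 0 | !df$icd_revision %in% c(9, 10) |
                 is.na(df$icd_code) | df$icd_code == "")
  if (length(bad))
    stop("malformed death record(s) at data row(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  df
}

#' Write / read a mortality grid as CSV
#'
#' Long layout: `unit`, `period_start`, `age_group_start`, `deaths`,
#' `person_years` (and `deaths_raw` when the grid carries a raw-count
#' attribute from [correct_pipeline()]).
#'
#' @param grid a [mortality_grid()].
#' @param path CSV file.
#' @return `write_mortality_grid` returns `path` invisibly;
#'   `read_mortality_grid` returns a [mortality_grid()] (with a `D_raw`
#'   attribute when present in the file).
#' @export
write_mortality_grid <- function(grid, path) {
  stopifnot(is_mortality_grid(grid))
  df <- data.frame(unit = grid$unit,
                   period_start = rep(grid$period_starts, each = nrow(grid$D)),
                   age_group_start = rep(grid$age_starts, ncol(grid$D)),
                   deaths = as.vector(grid$D),
                   person_years = as.vector(grid$N))
  raw <- attr(grid, "D_raw")
  if (!is.null(raw)) df$deaths_raw <- as.vector(raw)
  .write_csv(df, path)
  invisible(path)
}

#' @rdname write_mortality_grid
#' @export
read_mortality_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit", "period_start", "age_group_start", "deaths", "person_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("grid file is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[order(df$period_start, df$age_group_start), ]
  ages <- sort(unique(df$age_group_start))
  periods <- sort(unique(df$period_start))
  shape <- function(v) matrix(v, nrow = length(ages))
  g <- mortality_grid(shape(df$deaths), shape(df$person_years),
                      ages, periods, unit = df$unit[1])
  if ("deaths_raw" %in% names(df)) attr(g, "D_raw") <- shape(df$deaths_raw)
  g
}

#' Read completeness correction factors
#'
#' Accepts a CSV with columns `decade`, `factor` (optional `unit`) or a
#' YAML mapping of decade start year to factor.
#'
#' @param path file path.
#' @return a [correction_factors()] table.
#' @export
read_correction_factors <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    return(correction_factors(unlist(y)))
  }
  correction_factors(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read and validate a pipeline configuration
#'
#' YAML with the lattice (`age_group_starts`, `period_starts`), reference
#' period and cohort, the correction fraction, paths to the
#' correction-factor and standard-population tables (both optional), the
#' parameterization `mode`, the `seed`, and a `synthetic` section passed
#' to [synthetic_config()].
#'
#' @param path YAML file.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(age_group_starts = seq(20, 80, by = 5),
                   period_starts = seq(1980, 2015, by = 5),
                   ref_period = 1995, ref_cohort = 1945,
                   correction_fraction = 0.5,
                   mode = "factor", seed = 1L,
                   factors_path = NULL, standard_population_path = NULL,
                   synthetic = list())
  cfg <- utils::modifyList(defaults, cfg)
  if (is.unsorted(cfg$age_group_starts, strictly = TRUE) ||
      is.unsorted(cfg$period_starts, strictly = TRUE))
    stop("age and period bins must be strictly increasing")
  if (!cfg$mode %in% c("factor", "spline"))
    stop("mode must be 'factor' or 'spline'")
  if (cfg$correction_fraction < 0 || cfg$correction_fraction > 1)
    stop("correction_fraction must lie in [0, 1]")
  for (p in c(cfg$factors_path, cfg$standard_population_path))
    if (!is.null(p) && !file.exists(p))
      stop("configured file does not exist: ", p)
  structure(cfg, class = "pipeline_config")
}
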