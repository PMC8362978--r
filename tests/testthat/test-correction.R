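one_stratum <- function(B = 20, OC = 30, ON = 50, ILL = 40, INC = 10, NN = 0) {
  as_cause_tabulation(data.frame(
    unit = "u", period_start = 1980, age_start = 20,
    BREAST = B, OTHER_DEFINED_CANCER = OC, OTHER_DEFINED_NATURAL = ON,
    ILL_DEFINED = ILL, INCOMPLETE_CANCER = INC, NON_NATURAL = NN))
}

test_that("ICD-9 and ICD-10 codes map to the six cause classes", {
  expect_equal(classify_cause("C50", 10), "BREAST")
  expect_equal(classify_cause("C79", 10), "INCOMPLETE_CANCER")
  expect_equal(classify_cause("R98", 10), "ILL_DEFINED")
  expect_equal(classify_cause("174", 9), "BREAST")
  expect_equal(classify_cause("1749", 9), "BREAST")     # subcode truncation
  expect_equal(classify_cause("C50.9", 10), "BREAST")
  expect_equal(classify_cause(c("195", "197", "199"), 9),
               rep("INCOMPLETE_CANCER", 3))
  expect_equal(classify_cause(c("C76", "C77", "C78", "C80", "C97"), 10),
               rep("INCOMPLETE_CANCER", 5))
  expect_equal(classify_cause("785", 9), "ILL_DEFINED")
  expect_equal(classify_cause(c("E810", "812"), 9), rep("NON_NATURAL", 2))
  expect_equal(classify_cause(c("V89", "X70", "S02"), 10),
               rep("NON_NATURAL", 3))
  expect_equal(classify_cause(c("C34", "D20"), 10),
               rep("OTHER_DEFINED_CANCER", 2))
  expect_equal(classify_cause("162", 9), "OTHER_DEFINED_CANCER")
  expect_equal(classify_cause(c("I21", "D65"), 10),
               rep("OTHER_DEFINED_NATURAL", 2))
  expect_equal(classify_cause("410", 9), "OTHER_DEFINED_NATURAL")
  expect_error(classify_cause("XX", 10), "unparseable")
  expect_error(classify_cause("17", 9), "unparseable")
  expect_error(classify_cause("174", 8), "icd_revision")
})

test_that("ill-defined redistribution is proportional, partial and conservative", {
  tab <- one_stratum()
  out <- redistribute_ill_defined(tab, fraction = 0.5)
  # proportional shares of 50% of the 40 ill-defined deaths
  expect_equal(out$BREAST, 20 + 40 * 0.5 * 20 / 100)
  expect_equal(out$OTHER_DEFINED_CANCER, 30 + 40 * 0.5 * 30 / 100)
  expect_equal(out$OTHER_DEFINED_NATURAL, 50 + 40 * 0.5 * 50 / 100)
  expect_equal(out$ILL_DEFINED, 20)
  expect_equal(out$INCOMPLETE_CANCER, 10)   # untouched by step i
  expect_equal(sum(out[CAUSE_CLASSES]), sum(tab[CAUSE_CLASSES]))

  # no ill-defined deaths: identity
  expect_equal(as.data.frame(redistribute_ill_defined(one_stratum(ILL = 0))),
               as.data.frame(one_stratum(ILL = 0)))

  # fraction 1 with a single defined-natural class absorbing everything
  solo <- one_stratum(B = 0, OC = 0, ON = 8, ILL = 12, INC = 0)
  out <- redistribute_ill_defined(solo, fraction = 1)
  expect_equal(out$OTHER_DEFINED_NATURAL, 20)
  expect_equal(out$ILL_DEFINED, 0)

  # non-natural deaths never gain mass
  tab <- one_stratum(NN = 7)
  expect_equal(redistribute_ill_defined(tab)$NON_NATURAL, 7)

  # empty denominator: warn, leave in place
  empty <- one_stratum(B = 0, OC = 0, ON = 0, ILL = 5, INC = 0)
  expect_warning(out <- redistribute_ill_defined(empty), "left in place")
  expect_equal(out$ILL_DEFINED, 5)

  expect_error(redistribute_ill_defined(one_stratum(), fraction = 1.5),
               "\\[0, 1\\]")
})

test_that("incomplete-cancer redistribution spreads over specified cancers only", {
  out <- redistribute_incomplete_cancer(one_stratum())
  expect_equal(out$BREAST, 20 + 10 * 20 / 50)
  expect_equal(out$OTHER_DEFINED_CANCER, 30 + 10 * 30 / 50)
  expect_equal(out$INCOMPLETE_CANCER, 0)
  expect_equal(out$OTHER_DEFINED_NATURAL, 50)
  expect_equal(sum(out[CAUSE_CLASSES]), sum(one_stratum()[CAUSE_CLASSES]))

  # identity without incomplete deaths
  expect_equal(as.data.frame(redistribute_incomplete_cancer(one_stratum(INC = 0))),
               as.data.frame(one_stratum(INC = 0)))

  # zero breast share stays zero whatever the incomplete count
  out <- redistribute_incomplete_cancer(one_stratum(B = 0, INC = 25))
  expect_equal(out$BREAST, 0)
  expect_equal(out$OTHER_DEFINED_CANCER, 55)

  # no specified cancers at all: warn and leave
  expect_warning(
    out <- redistribute_incomplete_cancer(one_stratum(B = 0, OC = 0, INC = 9)),
    "left in place")
  expect_equal(out$INCOMPLETE_CANCER, 9)
})

test_that("completeness factors multiply by decade without rounding", {
  f <- correction_factors(c("1980" = 1.25, "1990" = 1.0))
  expect_equal(apply_completeness(40, 1987, f), 50.0)   # 1987 is a 1980s year
  expect_equal(apply_completeness(40, 1990, f), 40.0)   # identity factor
  expect_equal(apply_completeness(c(10, 10), c(1981, 1992), f), c(12.5, 10))
  expect_error(apply_completeness(1, 2005, f), "no completeness factor")
  expect_error(correction_factors(c("1980" = 0.9)), ">= 1")
})

test_that("the composed four-step correction matches hand enumeration", {
  tab <- one_stratum()
  res <- correct_pipeline(tab, correction_factors(c("1980" = 1.2)),
                          age_starts = 20, period_starts = 1980)
  # (20 registered + 4.0 from step i + 4.0 from step ii) * 1.2
  expect_equal(unname(res$D_corrected[1, 1]), 33.6)
  expect_equal(unname(res$D_raw[1, 1]), 20)

  # pipeline identity: no garbage classes, unit factors
  clean <- one_stratum(ILL = 0, INC = 0)
  res <- correct_pipeline(clean, unit_factors()[1, ],
                          age_starts = 20, period_starts = 1980)
  expect_equal(unname(res$D_corrected[1, 1]), 20)
})

test_that("correction is monotone in garbage counts and factors", {
  base <- correct_pipeline(one_stratum(), correction_factors(c("1980" = 1.2)),
                           age_starts = 20, period_starts = 1980)$D_corrected[1, 1]
  more_ill <- correct_pipeline(one_stratum(ILL = 60),
                               correction_factors(c("1980" = 1.2)),
                               age_starts = 20, period_starts = 1980)$D_corrected[1, 1]
  more_inc <- correct_pipeline(one_stratum(INC = 30),
                               correction_factors(c("1980" = 1.2)),
                               age_starts = 20, period_starts = 1980)$D_corrected[1, 1]
  bigger_factor <- correct_pipeline(one_stratum(),
                                    correction_factors(c("1980" = 1.5)),
                                    age_starts = 20, period_starts = 1980)$D_corrected[1, 1]
  expect_gt(more_ill, base)
  expect_gt(more_inc, base)
  expect_gt(bigger_factor, base)
})

test_that("correcting twice with unit factors and no garbage left is idempotent", {
  tab <- one_stratum()
  once <- redistribute_incomplete_cancer(redistribute_ill_defined(tab, 1))
  twice <- redistribute_incomplete_cancer(redistribute_ill_defined(once, 1))
  expect_equal(as.data.frame(twice), as.data.frame(once), tolerance = 1e-12)
})

test_that("record-level and aggregated paths give identical corrected grids", {
  cfg <- small_config(seed = 91, p_ill_defined = 0.2, p_incomplete = 0.15)
  reg <- generate_records(cfg)
  f <- unit_factors()
  by_records <- correct_pipeline(reg$records, f,
                                 age_starts = cfg$age_starts,
                                 period_starts = cfg$period_starts)
  tab <- tabulate_causes(reg$records, cfg$age_starts, cfg$period_starts)
  by_tab <- correct_pipeline(tab, f,
                             age_starts = cfg$age_starts,
                             period_starts = cfg$period_starts)
  expect_equal(by_records$D_corrected, by_tab$D_corrected, tolerance = 1e-12)
})

test_that("corrected grid tracks the generating truth on a well-populated registry", {
  # incomplete-coding plus under-registration is exactly invertible in
  # expectation: proportional redistribution is unbiased when miscoding is
  # cause-blind, and the decade factors invert registration exactly
  cfg <- synthetic_config(population_base = 5e5, p_ill_defined = 0,
                          p_incomplete = 0.08,
                          completeness = c("1980" = 0.8, "1990" = 0.85,
                                           "2000" = 0.92, "2010" = 0.97),
                          seed = 314)
  reg <- generate_records(cfg)
  f <- correction_factors(stats::setNames(1 / cfg$completeness,
                                          names(cfg$completeness)))
  corr <- correct_pipeline(reg$records, f)$D_corrected
  truth <- cfg$population_base * generate_true_rates(cfg)
  se <- sqrt(sum(truth))  # Poisson Monte-Carlo error of the sampled total
  expect_lt(abs(sum(corr) - sum(truth)), 3 * se)

  # with ill-defined miscoding on, the 50% partial redistribution is
  # conservative by construction: corrected stays between the registered
  # breast count and the truth, within a modest deficit
  cfg2 <- synthetic_config(population_base = 5e5, seed = 315)
  reg2 <- generate_records(cfg2)
  f2 <- correction_factors(stats::setNames(1 / cfg2$completeness,
                                           names(cfg2$completeness)))
  res2 <- correct_pipeline(reg2$records, f2)
  truth2 <- sum(cfg2$population_base * generate_true_rates(cfg2))
  expect_gt(sum(res2$D_corrected), sum(res2$D_raw))
  expect_lt(abs(sum(res2$D_corrected) / truth2 - 1), 0.10)
})
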