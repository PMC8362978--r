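#!/usr/bin/env Rscript
# Stage 3 — mortality rates.
#
# Age-specific, crude and directly standardized rates (Segi world
# standard, ages 20+) per quinquennium for the corrected grid, plus the
# first-to-last percent increases of the published standardized rates of
# the nine Northeast-Brazil states at the full correction stage.

suppressPackageStartupMessages(library(apcmort))

grid <- read_mortality_grid("results/corrected_grid.csv")
asr <- age_specific_rates(grid)
std <- direct_standardized_rate(asr, segi_standard())
crude <- crude_rate(grid)

message("standardized rate per 100,000 by quinquennium:")
message(paste(sprintf("  %d: %.2f", grid$period_starts, std), collapse = "\n"))
message(sprintf("mean standardized rate over the study window: %.2f",
                mean_period_rate(std)))
message(sprintf("percent change %d -> %d: %.1f%%",
                min(grid$period_starts), max(grid$period_starts),
                percent_change(std[1], std[length(std)])))

rates <- rbind(
  data.frame(unit = grid$unit,
             period_start = rep(grid$period_starts, each = nrow(asr)),
             age_group_start = as.character(rep(grid$age_starts, ncol(asr))),
             rate_per_100k = as.vector(asr)),
  data.frame(unit = grid$unit, period_start = grid$period_starts,
             age_group_start = "ALL", rate_per_100k = unname(crude)),
  data.frame(unit = grid$unit, period_start = grid$period_starts,
             age_group_start = "STD", rate_per_100k = unname(std)))
write.csv(rates, "results/rates.csv", row.names = FALSE)

inc <- rate_table_percent_increase()
message("\npublished fully-corrected rates, first-to-last percent increase:")
message(paste(sprintf("  %-20s %6.2f -> %6.2f  +%.1f%%", inc$locality,
                      inc$first, inc$last, inc$pct_change), collapse = "\n"))
write.csv(inc, "results/published_percent_increase.csv", row.names = FALSE)
message("wrote results/rates.csv and results/published_percent_increase.csv")
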