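#!/usr/bin/env Rscript
# Stage 5 — sequential sub-model comparison.
#
# The six-row deviance table (Age; Age-drift; Age-Cohort;
# Age-Period-Cohort; Age-Period; Age-drift) with chi-square p-values
# between adjacent rows, and the smallest adequate model at 0.05.

suppressPackageStartupMessages(library(apcmort))

grid <- read_mortality_grid("results/corrected_grid.csv")
tab <- sequential_table(grid)
print(tab)

write.csv(as.data.frame(tab), "results/model_table.csv", row.names = FALSE)
writeLines(capture.output(print(tab)), "results/model_table.txt")
message("wrote results/model_table.csv and results/model_table.txt")
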