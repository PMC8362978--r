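# apcmort

Age-period-cohort analysis of cancer mortality from imperfect vital
registration data.

## The problem

Breast-cancer mortality trends in regions with historically weak vital
registration — the motivating case is the nine states of Northeast
Brazil, 1980-2019 — cannot be read directly off registered death counts:
a substantial share of deaths is coded to ill-defined symptom codes or
to unspecified cancer sites, and registration coverage itself improved
decade by decade. Both distortions masquerade as epidemiological trend.
`apcmort` is for epidemiologists and biostatisticians who need to (a)
correct registered cause-specific death counts for miscoding and
under-registration, (b) compute directly standardized rates, and (c)
decompose the corrected trend into age, period and birth-cohort effects
with honest identifiability handling.

## The model

Deaths `D_ij` in 5-year age group `i` (20-24 ... 80+, I = 13) and 5-year
period `j` (1980-1984 ... 2015-2019, J = 8) with person-years `N_ij`:

    ln E[D_ij] = ln N_ij + mu + alpha_i + beta_j + gamma_k,   k = j - i + I

with K = I + J - 1 = 20 birth cohorts along the Lexis diagonals. Because
cohort = period − age the model is exactly collinear, so only estimable
functions are reported: the **net drift** (the common linear trend,
equal to the sum of the period and cohort slopes), slope-free **period
and cohort curvatures** as relative risks against the reference period
(1995-1999) and reference cohort (1945-1949), and the **longitudinal age
curve** (fitted rates along the reference cohort). Sub-models (Age,
Age-drift, Age-Cohort, Age-Period, full APC) are compared in the
standard six-row sequential deviance table with chi-square p-values
between adjacent rows.

Upstream of the model, registered breast-cancer deaths are corrected in
four steps: (i) proportional redistribution of 50% of ill-defined deaths
among defined natural causes, (ii) proportional redistribution of
incomplete cancer diagnoses (195-199 / C76-C80, C97) among specified
cancers, (iii) summation of both breast shares with the registered
breast deaths, and (iv) multiplication by decade-specific registration
completeness factors.

A synthetic registry generator with a known generating surface and
controllable corruption (miscoding probabilities, decade-dependent
completeness) backs the entire validation suite; no external data
download is needed anywhere.

## Worked example

The `analysis/` scripts run the whole workflow on a bundled demo
configuration (one synthetic state, 300,000 person-years per cell,
corruption on):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_correct.R
Rscript analysis/03_rates.R
Rscript analysis/04_apc_fit.R
Rscript analysis/05_model_table.R
```

Stage 2 prints the effect of the correction — registered breast-coded
deaths 3813 become 4869.7 (+27.7%) against a generating truth of 5227
(the 50% partial redistribution is deliberately conservative):

```
registered breast-coded deaths: 3813
after correction: 4869.7 (+27.7%); generating truth: 5227
```

Stage 4 fits the APC model to the corrected grid and reports the
estimable summaries:

```
<apc_fit> model apc (factor parameterization)
  residual deviance 79.371 on 66 df
  net drift: 0.0846 per 5 years (annual 0.0169, 95% CI 0.0105 to 0.0233)
  period RR range 0.932-1.093 (ref 1995-1999)
  cohort RR range 0.781-1.634 (ref 1945-1949)
net drift: 1.71% per year (95% CI 1.06% to 2.36%)
```

i.e. the corrected rates rise about 1.7% per year, and women of recent
cohorts carry up to a 1.63-fold risk relative to the 1945-1949 cohort.
Stage 5 prints the sequential deviance ladder and the smallest adequate
model. Equivalent programmatic use:

```r
library(apcmort)
cfg  <- synthetic_config(population_base = 3e5, seed = 20250101)
reg  <- generate_records(cfg)
f    <- correction_factors(setNames(1/cfg$completeness, names(cfg$completeness)))
grid <- correct_pipeline(reg$records, f,
                         person_years = matrix(3e5, cfg$I, cfg$J))
fit  <- fit_apc(grid)
sequential_table(grid)
```

The package also ships the published standardized-rate table for the
nine Northeast-Brazil states; `rate_table_percent_increase()` reproduces
the first-to-last quinquennium increases (62.1% in Alagoas up to 222.2%
in Maranhão, all nine states above 60%).

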