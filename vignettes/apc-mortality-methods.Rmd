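---
title: "Methods: registry correction and identifiable age-period-cohort modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry correction and identifiable age-period-cohort modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcmort)
```

## The scientific problem

Long-run cancer mortality trends estimated from vital registration
systems are distorted by two kinds of data-quality problems: *miscoding*
(deaths assigned to ill-defined symptom codes, or to unspecified cancer
sites) and *under-registration* (deaths that never enter the system at
all). Both vary strongly by place and by decade, so uncorrected trends
confound real epidemiology with improving registration. This package
implements a complete pipeline for breast-cancer mortality of women aged
20 and over on a quinquennial Lexis lattice: correction of the registered
death counts, direct age standardization, and an age-period-cohort (APC)
Poisson model reported through estimable functions. A synthetic registry
generator with known generating truth makes every stage testable without
access to any real registry extraction.

## The APC model and its identifiability problem

Deaths $D_{ij}$ in age group $i = 1,\dots,I$ (5-year groups, 20-24 up to
the open 80+ group, $I = 13$) and period $j = 1,\dots,J$ (5-year periods,
$J = 8$) with person-years $N_{ij}$ are modelled as Poisson with log link
and offset:

$$\ln E[D_{ij}] = \ln N_{ij} + \mu + \alpha_i + \beta_j + \gamma_{k},
\qquad k = j - i + I ,$$

with $K = I + J - 1$ synthetic birth cohorts indexed along Lexis
diagonals (20 cohorts for the default design, labelled by
$\text{period start} - \text{age start}$: 1900, 1905, ..., 1995).

Because cohort = period − age, the three time scales are exactly
collinear: adding a linear trend $c \cdot j$ to the period effects and
subtracting $c \cdot k$ from the cohort effects (with compensating age
and intercept shifts) leaves every fitted mean unchanged. Only
*estimable functions* are reported:

* **net drift** — the common linear trend of the log rates, the sum of
  the period and cohort slopes, reported per 5-year step and annualized;
* **curvatures** — departures of the period and cohort effects from
  linearity, which are invariant to the trend allocation;
* the **longitudinal age curve** — fitted rates along the reference
  cohort.

### Parameterization

The design matrix contains: an age term (factor with one level per group
by default), a single *drift* column (period index centred at the
reference period), and period and cohort *curvature bases*. A curvature
basis for a dimension of length $n$ is an orthonormal basis of the
space orthogonal to the constant and the linear trend in the category
index ($n - 2$ columns), built by QR decomposition. Effects assembled
from these columns have exactly zero mean and zero slope, so the drift
column carries the entire linear time trend and the design is full rank —
no constraint juggling, no aliased coefficients. Curvature contrasts are
re-zeroed at the reference period (1995-1999) and reference cohort
(1945-1949), where the relative risk is consequently exactly 1 with a
zero-width interval. Detrending uses unweighted (equal category weight)
least squares; other software conventions weight by marginal counts, so
curvature values can differ slightly across implementations even though
fitted means agree.

The reference choices follow the convention of anchoring at central,
well-observed categories: central cohorts are observed at many more ages
than the extreme diagonals.

### Slope allocation modes

`fit_apc(..., drift_to =)` reports period and cohort either as pure
curvatures (`"none"`, the default) or with the full fitted trend
allocated onto one dimension (`"period"` or `"cohort"`), for comparison
with software that reports longitudinal cohort effects. The invariance
of fitted cell means across these modes is a tested property (relative
differences below $10^{-8}$).

### Factor versus spline mode

The default is one parameter per category (residual df on the full
13 × 8 design: Age 91, Age-drift 90, Age-Cohort 72, APC 66, Age-Period
84). A natural-spline mode (`apc_design(mode = "spline")`, default df 8
/ 5 / 6 for age / period / cohort) is provided because published APC
analyses frequently smooth the three dimensions, which yields larger
residual df than the factor parameterization; the spline df are
configurable and no particular published choice is asserted. Spline
bases are projected off the constant-plus-linear span so drift keeps its
meaning.

### Numerical choices

Fitting is iteratively reweighted least squares (`stats::glm.fit`),
relative convergence tolerance $10^{-10}$, at most 100 iterations,
failure to converge is an error. The covariance is the inverse observed
information. Corrected death counts are real-valued; the Poisson
deviance formula $2\sum d \ln(d/\hat\mu) - (d - \hat\mu)$ extends
smoothly and is used unchanged. Deviances are validated against an
independent damped-Newton maximizer of the same likelihood to $10^{-6}$
on small grids.

## The sequential model comparison

Nested sub-models are compared by deviance differences on chi-square
distributions, arranged in the conventional six-row ladder (Age;
Age-drift; Age-Cohort; Age-Period-Cohort; Age-Period; Age-drift), each
row tested against the adjacent previous row; the drift row appears
twice, sharing one fit, and the final drift row is tested against
Age-Period. Because every sub-model here is built from the same drift +
curvature columns, the two ladders Age → Age-drift → Age-Cohort → APC
and Age → Age-drift → Age-Period → APC are exactly nested and deviance
is monotone along both (a tested property).

The "best model" annotation applies the smallest-adequate-model rule at
$\alpha = 0.05$: a curvature is kept only if removing it from the full
model significantly worsens fit. One caveat is intrinsic to APC
structure: curvature in the cohort dimension is partially expressible
through age and period columns (the diagonal relation), so attribution
between the period and cohort tables is sharp only for the genuinely
diagonal component — the model-comparison tests, not the effect plots,
are the arbiter.

## The four-step correction

Given records classified into six cause classes (breast cancer 174 /
C50; other specified cancer 140-208 / C00-C97 + D00-D48; incomplete
cancer diagnosis 195-199 / C76-C80 + C97; ill-defined 780-799 /
R00-R99; other specified natural; external), the corrected breast count
per cell is

$$D^{\mathrm{corr}} = \left( D_{\mathrm{breast}} + G_{\mathrm{ill}} +
G_{\mathrm{inc}} \right) \times F_{\mathrm{decade}},$$

where $G_{\mathrm{ill}}$ is the breast share of 50% of the ill-defined
deaths redistributed proportionally over defined natural causes,
$G_{\mathrm{inc}}$ the breast share of the incomplete cancer diagnoses
redistributed proportionally over specified cancers, and $F$ a
decade-specific completeness factor ($\ge 1$, supplied as input — the
pipeline does not estimate coverage).

Design choices that the procedure's verbal description leaves open were
resolved as follows:

* **Strata for step (i).** Redistribution happens within unit × period
  × age cell by default, because pooling across ages or periods would
  let the redistribution itself reshape the Lexis surface; a coarse
  unit-level mode (`strata = "unit"`) exists for sensitivity analysis.
* **Parallel shares.** Steps (i) and (ii) both compute their
  proportional shares from the *original* registered tabulation and the
  two breast-cancer gains are then summed — neither step sees the
  other's output. Sequential composition would make the result depend
  on step order.
* **Code list.** The incomplete-diagnosis set is the deduplicated
  $\{195\text{-}199\} \cup \{C76\text{-}C80, C97\}$; the ill-defined
  chapters are taken from the ICD chapter definitions (ICD-9 780-799,
  ICD-10 R00-R99).
* **Real-valued counts.** Corrected counts are never rounded inside the
  pipeline; rounding only at report time avoids compounding bias over
  four steps. The Poisson machinery accepts real-valued counts.
* **Small cells.** A stratum holding garbage-coded deaths but no
  eligible recipients keeps those deaths in place with a warning rather
  than failing: empty denominators are routine in sparse young-age
  cells.

Conservation (steps i-ii never change a stratum's total), monotonicity
(corrected counts non-decreasing in every garbage count and factor) and
equivalence of the record-level and pre-aggregated input paths are
tested properties.

The 50% fraction deliberately under-corrects relative to a
corruption process in which *all* miscoded natural deaths are
recoverable: it encodes the belief that only about half of ill-defined
deaths stem from genuinely natural, attributable causes. Consequently,
on synthetic data where ill-defined miscoding is cause-blind, the
corrected count sits slightly below the generating truth — the
validation suite checks exact mean recovery in the invertible regime
(incomplete-coding plus under-registration only) and bounded deficit
otherwise.

## Rates and standardization

Age-specific rates are $10^5 \, D_{ij}/N_{ij}$; crude and truncated
(pooled above an age floor) rates aggregate numerators and denominators
before dividing. Direct standardization uses the Segi world standard
population (Doll-Hill modification) restricted to ages 20+, with the
open 80+ weight pooling the 80-84 and 85+ classes (weight 1000); the
weights ship as a clearly labelled data file and any alternative
standard can be supplied. Truncated rates are computed per quinquennium
(the analysis resolution); a per-year mode of the generator supports
annual variants. Period averages of standardized rates are offered both
as simple means and person-year-weighted means, since published
period summaries rarely state which convention they use.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` fixes the generating truth: a log-linear APC
surface ($\mu = -9$ baseline, age effects rising steeply over ~5.3 log
units with a mild old-age flattening, small period curvature, cohort
effects carrying a 0.05-per-quinquennium secular drift with extra
curvature in recent cohorts), 1e6 person-years per cell by default
(roughly a mid-sized state's female age group over five years), and the
corruption process: cause-blind miscoding of cancers to incomplete
codes (8%), of natural deaths to ill-defined codes (10%), and
decade-dependent registration (80% / 85% / 92% / 97% across the four
decades, echoing the documented improvement of vital registration in
the region). The empirical shares of garbage codes per state and decade
are not published, so these defaults are plausible free parameters, not
calibrated values.

Deaths are simulated at 5-year-cell resolution by default (the analysis
resolution), with uniform per-year disaggregation available. ICD
revision switches at 1996. Non-natural deaths are generated but never
receive redistributed mass. Randomness is confined to each call via a
saved-and-restored RNG state, so identical seeds give byte-identical
registries and the caller's random stream is untouched.

The generator does *not* emulate: certification chains and associated
causes (the analysis uses underlying cause only), cause-dependent
miscoding propensities, migration or population error in the
denominators, or the proprietary binary formats of real registry
downloads. Passing tests therefore demonstrate the pipeline's internal
correctness and statistical calibration under a faithful-but-idealized
corruption model, not fidelity to any particular registry's error
structure.

## Validation problem sizes

The test battery uses expectation-valued grids (deviance ~ 0, exact
recovery of drift and curvatures to $10^{-6}$), ten random 4 × 3 grids
against the independent Newton oracle, 50 seeded stochastic registries
at 1e6 person-years per cell for drift CI coverage (coverage at least
90% required), and a 1e5-person-year end-to-end round trip with
corruption off, which must reproduce the sampled breast grid exactly.
These sizes were chosen so the full suite exercises every code path at
well-conditioned scales while remaining quick to run.

## Known limitations

* Completeness factors are inputs; no death-distribution method for
  estimating them is included.
* Wald intervals on the log scale can undercover for very sparse cells;
  the first and last cohort diagonals rest on single cells and are
  retained (not trimmed) by default, so their intervals are wide and
  their point estimates unstable — a trim is available downstream by
  subsetting the effect tables.
* The curvature decomposition uses unweighted detrending; comparisons
  with weighted-detrending software will show small, purely
  presentational differences.
* The correction assumes miscoding within a cell is cause-blind;
  differential miscoding by cause would bias the proportional shares.
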