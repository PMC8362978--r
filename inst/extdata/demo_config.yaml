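# Demonstration pipeline configuration: a single synthetic state observed
# on the 13 x 8 Lexis lattice (ages 20-24 ... 80+, periods 1980-1984 ...
# 2015-2019), with registry corruption on and completeness factors taken
# as the inverse of the generator's registration probabilities.
seed: 20250101
mode: factor
ref_period: 1995
ref_cohort: 1945
correction_fraction: 0.5
synthetic:
  population_base: 3.0e5
  p_ill_defined: 0.10
  p_incomplete: 0.08
  unit: DEMO
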