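# beanrisk

Probabilistic health-risk assessment of potentially toxic elements (As,
Cd, Cr, Hg, Pb) in beans and similar staple foods, for food-safety
scientists and exposure assessors. The package covers the whole desk
workflow: preparing left-censored (non-detect) concentration surveys,
descriptive statistics with regulatory maximum-limit screening,
correlation and clustering analyses, and a seeded Monte Carlo engine that
turns concentration distributions and population exposure parameters into
non-carcinogenic and carcinogenic risk distributions with sensitivity
decomposition. A synthetic-data generator with known ground truth makes
every step testable without access to raw survey data.

## The model

For each element and population group, the estimated daily intake is

```
EDI = (C × EF × ED × IR × f) / (BW × AT × 1000)      [mg/kg/day]
```

with `C` the concentration in the food (mg/kg), `EF` the exposure
frequency (day/year), `ED` the exposure duration (year), `IR` the
ingestion rate (g/day), `f` a toxic-fraction multiplier (the inorganic
share of total As, 0.72; 1 for the other elements), `BW` the body weight
(kg) and `AT` the averaging time (day). Risk metrics are

```
THQ = EDI / RfD          target hazard quotient (RfD: reference dose;
                         Pb uses the FAO/WHO TDI 0.0036 mg/kg/day)
HI  = Σ THQ              hazard index over elements
CR  = EDI × SF           carcinogenic risk (As only, SF = 1.5 per mg/kg/day)
```

`HI > 1` flags potential non-carcinogenic risk; `CR` is conventionally
acceptable between 1e-6 and 1e-4. Monte Carlo propagation draws `C` from
lognormal distributions (moment-fitted to reported mean ± SD), `EF` from
a triangular, `ED` from a uniform and `BW` from a truncated normal
distribution per population group, and summarises the resulting THQ / HI
/ CR draws as percentiles, exceedance probabilities and
contribution-to-variance sensitivity shares (normalised squared Spearman
correlations, the convention of spreadsheet risk tools). See
`vignette("beanrisk-methods")` for modelling choices and limitations.

## Worked example

```r
library(beanrisk)

rd <- run_simulation(pooled_concentration_specs(), "children",
                     n_iter = 10000, seed = 42)
rd
#> <risk_distribution> children, 10,000 iterations, seed 42
#>   HI: mean 0.562, P50 0.506, P(HI > 1) 9.68%
#>   CR(As): mean 4.06e-05

tidy(rd)
#> # A tibble: 28 × 4
#>   population output statistic  value
#> 1 children   THQ-As mean      0.125
#> 2 children   THQ-As P50       0.0995
#> ...
#> 5 children   THQ-Cd mean      0.409
#> 8 children   THQ-Cd P95       0.887

exceedance(rd, "HI", 1)
#> # A tibble: 1 × 6
#>   population output threshold percent    se n_iter
#> 1 children   HI             1    9.68 0.296  10000

sensitivity(rd)
#> Contribution to variance of HI (normalized-squared-spearman)
#>   input      rho   share
#> 1 ED      0.817   70.7
#> 2 C_Cd    0.418   18.5
#> 3 EF      0.227    5.48
#> ...
```

Reading: the mean hazard index for children is 0.56 and its median 0.51
— below the benchmark of 1 — but 9.7% of iterations exceed 1, so a
non-negligible upper tail of the exposed population carries potential
non-carcinogenic risk, driven mostly by exposure duration and the Cd
concentration (together ~89% of HI variability). The mean As
carcinogenic risk, 0.41 × 10⁻⁴, stays inside the acceptable band.

The same engine runs from data rather than published summaries:

```r
records <- generate_samples(generator_scenario(seed = 1)) |>   # or read_concentration_csv()
  substitute_nondetects()                                      # WHO LOD/2 rule
summarize_concentrations(records)                              # medians, P95, >ML counts
spearman_matrix(records, by = "bean_type")                     # r, p, strength category
cluster_areas(records, k = 3)                                  # Ward clustering of areas
run_simulation(fit_concentration_specs(records), "adults", n_iter = 10000, seed = 1)
```

`run_pipeline(run_config(...))` chains all stages and writes CSV/JSON
artifacts plus a manifest; `inst/cli/beanrisk.R` is a thin command-line
wrapper around it.

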