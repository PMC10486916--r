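---
title: "Methods: probabilistic risk assessment of toxic elements in beans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic risk assessment of toxic elements in beans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beanrisk)
```

## Scope and model

beanrisk estimates the dietary health risk that consumption of beans
carrying traces of As, Cd, Cr, Hg and Pb poses to three population
groups (children, teens, adults). The deterministic core is the chronic
daily dose

$$\mathrm{EDI} = \frac{C \cdot EF \cdot ED \cdot IR \cdot f}{BW \cdot AT
\cdot 1000},$$

from which the target hazard quotient $\mathrm{THQ} = \mathrm{EDI} /
\mathrm{RfD}$, the hazard index $\mathrm{HI} = \sum_e \mathrm{THQ}_e$
and the carcinogenic risk $\mathrm{CR} = \mathrm{EDI} \times SF$ follow.
The stochastic layer draws the inputs per iteration — concentration $C$
lognormal, exposure frequency $EF$ triangular, exposure duration $ED$
uniform, body weight $BW$ normal truncated at zero, ingestion rate and
averaging time fixed — and summarises the output draws.

## Parameters and defaults

`default_element_tox()` carries the toxicological constants: reference
doses 0.0003 (inorganic As), 0.0001 (Cd), 1.5 (Cr) and 0.0001 (Hg)
mg/kg/day, the FAO/WHO tolerable daily intake 0.0036 mg/kg/day for Pb
(used in the RfD slot, with its provenance kept in `rfd_basis`), the
oral slope factor 1.5 (mg/kg/day)$^{-1}$ for inorganic As, and the
inorganic fraction $f = 0.72$ of total As in crops. Cr is assessed as
total Cr against the 1.5 mg/kg/day reference dose; with bean-level Cr
concentrations this yields quotients around $10^{-5}$, i.e. the zeros of
a two-decimal report. `default_populations()` carries the exposure
parameters: ingestion rates 32.9 / 58.87 / 42.75 g/day, body weights
16.68 ± 1.48 / 46.25 ± 1.18 / 57.03 ± 1.10 kg, exposure frequency
Triangular(180, 345, 365) day/year for all groups, exposure durations
Uniform(1, 7) / (8, 25) / (26, 70) year and averaging times 2190 / 5475
/ 18250 days.

Two parameter-table quirks are deliberate. First, the averaging time is
fixed per group while the exposure duration is random, so $EF \cdot ED$
can exceed $AT$ in some draws (about a third of adult draws); the engine
implements the table as stated and reports the affected fraction in
`meta$ef_ed_exceeds_at_frac` rather than renormalising. Second, the
ingestion rate is nominally "normal" but no spread is published, so it
is treated as fixed; a `dist_normal()` can be supplied through
`exposure_specs` where a spread is available.

### Where the inorganic-As fraction applies

The published account of this model is ambiguous: the text says total As
is converted to inorganic As (× 0.72) before computing THQ, yet the
printed THQ table and the HI exceedance certainties are consistent only
with *total* As in the non-carcinogenic pathway, while the printed CR
means require the 0.72 factor. beanrisk therefore defaults to applying
$f$ in the carcinogenic pathway only (`inorganic_as_in_thq = FALSE`),
which reproduces the published tables; setting the flag to `TRUE` gives
the toxicologically stricter reading (inorganic As is the species the
RfD refers to) at the cost of departing from the published THQ-As
values by roughly a third. This is a reporting-consistency choice, not a
toxicological judgement.

## Distributions and sampling

Concentration lognormals are parameterised by moment matching:
$\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$, so the
fitted distribution's analytic mean and SD equal the reported $m \pm s$
exactly (`fit_lognormal_moments()`; `log1p` keeps the fit stable as $s
\to 0$). All sampling is by inverse transform, which makes every draw a
deterministic function of the seed; lower truncation re-maps the
uniforms into $[F(\text{low}), 1)$, equivalent in distribution to
rejection sampling but loop-free. With the published body-weight spreads
the truncation at zero is numerically invisible (> 11 SDs from zero).

Correlated draws go through a Gaussian copula: a Spearman target $r_s$
is converted to the latent Pearson scale by the exact bivariate-normal
relation $\rho = 2\sin(\pi r_s / 6)$, latent normals are drawn with
covariance $\rho$ and pushed through each marginal's quantile function.
A target that is not positive semi-definite on the latent scale is an
error unless `repair = TRUE`, in which case negative eigenvalues are
clipped and the matrix rescaled to unit diagonal — never silently: the
matrix actually used is attached to the output. Risk runs draw all
inputs independently by default, since only marginal distributions are
published for them; cross-element concentration correlation can be
switched on via `conc_spearman`.

## Data preparation choices

Non-detects follow the WHO low-content rule: within each (bean type,
element) group, censored values become LOD/2. The rule is endorsed up to
a censored proportion of 60%; at exactly 60% substitution still applies,
above it the group is substituted the same way but flagged
`above_who_threshold`, leaving the judgement to the analyst. No
Kaplan–Meier or regression-on-order-statistics estimators are offered —
substitution is the method being mirrored.

All quantiles in the package — summary P95s, risk percentiles — use
linear interpolation between order statistics (R's default type 7), a
single convention chosen because none is published. Maximum-limit
exceedance is strict (`value > ML`); boundary-equal values do not count.
Spearman correlations use `stats::cor.test` with tie-corrected ranks;
strength labels (weak 0.01–0.39, moderate 0.40–0.59, strong 0.60–0.79,
very strong 0.80–1) are applied to $|r|$ rounded to two decimals, which
is the only total reading of the printed band edges that also labels
$r = 0.399$ "moderate" as the source account does; below 0.01 the label
is "negligible". Area clustering standardises each element's mean
profile to zero mean and unit SD before Ward linkage (`ward.D2` on
Euclidean distances) because element scales span two orders of
magnitude; the switch is exposed (`standardize = FALSE`) since the
original analysis does not state its scaling.

## Sensitivity analysis

Contribution to variance is the normalised-squared-Spearman convention
of spreadsheet Monte Carlo tools: share$_i$ = $100 \cdot \rho_i^2 /
\sum_j \rho_j^2$ with $\rho_i$ the rank correlation between input $i$
and the output. Rank scale keeps the measure robust to the lognormal
skew; it remains a correlation measure, not a functional variance
decomposition (Sobol indices are out of scope), and shares of
correlated inputs are not additive in general — with independent inputs,
as in the default runs, the interpretation is clean.

## Synthetic data

`generator_scenario()` emulates the survey the analysis assumes: 692
samples split over 7 bean types (307 black, 88 broad, 43 mung, 104
soybean, 51 red, 12 kidney, 87 pea), 11 sampling areas drawn uniformly,
5 elements per sample with lognormal marginals, Gaussian-copula
correlation, and value-threshold censoring (a draw below its element's
LOD becomes a non-detect carrying that LOD — the mechanism by which
ICP-MS non-detects actually arise). Per-type means come from the
published per-type table; per-type SDs reuse the pooled coefficient of
variation scaled by the type mean, because the published per-type SD
column duplicates its mean column and is evidently a typesetting
artefact. Default LODs derive from the assay's LOQs divided by 3.3. The
default correlation targets plant only the published pairs (kidney-bean
Cd–Pb 0.934 and Cd–Hg 0.746, black-bean Cd–As 0.720, red-bean Pb–As
0.701, mung-bean Cd–Pb 0.792) over a pooled baseline (Cd–Pb 0.399,
Cd–As 0.524); the kidney-bean combination is jointly infeasible with
zeros elsewhere, so its matrix is PSD-repaired at construction and the
planted values there are approximate by design.

What the generator does *not* emulate matters for interpreting green
tests: real surveys show far heavier concentration tails (single-sample
maxima tens of SDs above the mean), per-area mean shifts, per-laboratory
LODs (the real survey censors most Hg measurements; the default LODs
censor almost nothing), and non-lognormal shapes. Passing
parameter-recovery tests therefore demonstrates the pipeline's
correctness, not that field data meet its assumptions.

## Numerical and testing choices

Default runs use 10,000 iterations — the count at which the iteration
ladder (5,000 / 10,000 / 50,000, `convergence_check()`) shows HI
percentile drift well under 2% — and complete in well under a second per
population; property tests that need tighter Monte Carlo error (moment
convergence, copula marginal preservation) use $10^5$–$10^6$ draws of a
single quantity. Degenerate reductions are exact: with every input
`dist_fixed`, the engine reproduces the closed-form equations to
floating-point round-off, which is the backbone of the deterministic
acceptance check (adult mean CR $0.22 \times 10^{-4}$ at mean
parameters). Reproduction of the published stochastic table from the
pooled moment fit is tight but not exact — the original analysis
evidently fitted more skewed concentration distributions (its THQ
mean/median ratios exceed what a CV ≈ 0.37 lognormal can produce), so
published medians sit slightly below and exceedance certainties slightly
above the pooled-fit values; the comparison tolerances (±0.06 absolute
or ±15% relative on table cells, ±4 / ±1 percentage points on HI
certainties) absorb both this convention gap and Monte Carlo error.

## Limitations

Single-route (ingestion) exposure only; no toxicokinetics, no
age-interpolated exposure, no mixture interactions beyond THQ
additivity; CR is computed for As only, the single element with a
published oral slope factor here; concentration uncertainty and
population variability are not separated (one-dimensional Monte Carlo).
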