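---
title: "Methods: PM2.5-attributable mortality with GEMM and abridged life tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PM2.5-attributable mortality with GEMM and abridged life tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhia)
```

## The problem

Long-term exposure to fine particulate matter (PM2.5) raises adult
mortality from non-communicable diseases and lower respiratory
infections. A health impact assessment (HIA) asks: if a region's
annual-mean PM2.5 had been at some counterfactual level — the WHO air
quality guideline of 5 μg/m³, or a proposed national standard of
15 μg/m³ — how many of the deaths that occurred would not have? `pmhia`
implements that counterfactual calculation for administrative units
(districts nested in provinces) with sex-aggregated demography in 5-year
age bands, reporting attributable deaths (AD), years of life lost (YLL),
loss of life expectancy at birth (LLE), and rates per 100,000, each with
95% uncertainty intervals.

## Risk models

**GEMM.** The Global Exposure Mortality Model expresses the hazard ratio
at annual-mean concentration $C$ as

$$\mathrm{HR}(z) = \exp\!\left\{\theta \,\log\!\left(1 + \frac{z}{\alpha}\right)
\frac{1}{1 + \exp\!\left(-\frac{z - \mu}{\nu}\right)}\right\},
\qquad z = \max(0,\, C - 2.4),$$

with an age-specific log-hazard scale $\theta$ (and standard error) and
shared shape parameters $\alpha = 1.6$, $\mu = 15.5$, $\nu = 36.8$ μg/m³
for the NCD+LRI outcome. The 2.4 μg/m³ offset is part of the published
fit (the lowest exposure observed in the pooled cohorts) and is kept
fixed; policy counterfactuals enter only through the attributable
fraction below. The parameter table ships as a plain-text CSV
(`inst/extdata/gemm_ncd_lri.csv`) and can be replaced by path. The
published table's terminal age group is 80+, so its $\theta$ serves both
the 80–84 and 85+ bands here.

**Log-linear.** For comparison with AirQ+-style assessments, a
log-linear model uses an all-cause relative risk per 10 μg/m³ (default
1.062, 95% CI 1.040–1.083, the Hoek et al. meta-analysis that AirQ+
ships), $\mathrm{RR} = 1.062^{(C - C_{cf})/10}$, applicable to adults
30+.

**Attributable fraction.** For either model,
$\mathrm{AF} = 1 - \mathrm{HR}(C_{cf})/\mathrm{HR}(C)$, clamped to zero
when the observed concentration does not exceed the counterfactual: units
at or below the threshold report exactly zero burden (they are kept in
the outputs with a `below_counterfactual` flag rather than dropped, so
sums and maps stay total).

## From fractions to burden

Per district and 5-year adult band $a$:
$\mathrm{AD}_a = \text{population}_a \times \text{death rate}_a \times
\mathrm{AF}_a$; $\mathrm{YLL}_a = \mathrm{AD}_a \times e_a$, where $e_a$
is the remaining life expectancy of band $a$ in the district's baseline
abridged life table (the band-start $e_x$ as constructed, not a midpoint
interpolation). LLE is the gain in life-table $e_0$ when the
attributable deaths are removed from the schedule — computed internally
in days and reported in years (÷ 365.25). Rates divide counts by the
unit's total all-age population × 100,000; an adults-only denominator is
available (`rate_denominator = "adults-only"`). The total-population
default follows the scenario-table convention of provincial HIA reports,
whose printed rates are consistent with all-age denominators.

## Abridged life table

Standard 5-year construction: $ {}_nq_x = n\,{}_nM_x / (1 + (n -
{}_na_x)\,{}_nM_x)$ with ${}_na_x = n/2$ for all closed intervals
(sex-aggregated 5-year registry data cannot support infant-separation
refinements; a Coale–Demeny-style $a_0$ override is exposed through the
`nax` argument), survivorship from a radix of 100,000, terminal
person-years $l_x / M_x$ (constant-hazard tail), $e_x = T_x / l_x$. The
open interval defaults to 85+ and is configurable. A rate extreme enough
to push $ {}_nq_x$ above 1 is clamped with a warning.

The construction is verified two ways. A cohort microsimulation samples
a million individual lifetimes from the same piecewise model (band death
probabilities with uniform deaths inside closed intervals, exponential
tail) by inverse-CDF and must agree with the table's $e_0$ and every
$e_x$ to within 0.5% — a Monte-Carlo check of the actuarial recursion
through an entirely separate code path. Separately, a continuous model
with constant hazard within each band — a different convention, sharing
no formulas with the table — must agree on $e_0$ to within 0.5%. The two
conventions genuinely diverge beyond that at the oldest closed band when
old-age rates are high (the uniform-deaths approximation is coarsest
there), which is why the convention-free claim is made for $e_0$ only.

## Uncertainty

Intervals are propagated end-to-end by evaluating the whole pipeline at
$\theta$, $\theta - 1.96\,\mathrm{SE}$, and $\theta + 1.96\,\mathrm{SE}$
per age group, treating parameter uncertainty as perfectly correlated
across ages — the conventional GEMM practice, and deterministic. Because
the hazard ratio is monotone in $\theta$, the bounds are guaranteed
ordered at every aggregation level. A seeded Monte-Carlo alternative
(normal draws on $\theta$, or on $\log \mathrm{RR}$ for the log-linear
model) is available via `n_draws`. Baseline death rates and populations
are treated as fixed: the demographic inputs carry no published
uncertainty.

## Aggregation

Counts (AD, YLL) are additive: district values sum to provinces and to
the study region. Rates are always recomputed from summed counts over
summed denominators, never averaged. Aggregate LLE is recomputed from
the pooled (summed) mortality schedule of the group with the pooled
attributable deaths removed — a population-weighted average of district
LLEs is available via `lle_aggregation`, but pooling is the default
since LLE is a nonlinear functional of the schedule.

## The model comparison

`run_comparison()` pairs province-level AD rates under GEMM and the
log-linear model at the same counterfactual (default 5 μg/m³; the
log-linear path restricted to ages 30+, as its risk estimate requires).
The two columns deliberately use different denominators: GEMM per the
configured (total) population, log-linear per its own exposed 30+
population, which is how AirQ+ reports its rate output. This matters for
interpretation: across 15–40 μg/m³ the GEMM NCD+LRI attributable
*fraction* actually exceeds the log-linear one for most ages (the
log-linear curve only catches up near the top of the range for the
flattest old-age GEMM curves), so the familiar observation that
AirQ+-style rates are higher than GEMM rates is largely a denominator
effect, not a risk-function effect. The denominator convention is
recorded in the result's `denominators` attribute.

## Synthetic study region

The generator exists so the whole pipeline is testable without any data
download, and its defaults are the study conditions: 11 provinces whose
annual means span 15.8–40.8 μg/m³, adult (25+) populations between 0.29
and 5.8 million, and crude 25+ death rates in 4.1–8.3 per 1,000.
Province targets can also be pinned to the packaged province table
(`simulate_study_region(config, provinces = vietnam_provinces())`).

*Demography.* Age structure is a quasi-stable pyramid — weights
$\propto e^{-rx} S(x)$ with growth rate $r = 0.015$/yr over the baseline
survivorship — and mortality is Gompertz–Makeham,
$\mu(x) = a e^{bx} + c$ with $a = 3.5 \times 10^{-5}$, $b = 0.095$/yr,
$c = 6 \times 10^{-4}$/yr (unscaled $e_0 \approx 75$ y), linearly
rescaled per district so the crude 25+ rate hits its target; targets
outside the achievable range are rejected with that range. Deaths are
rounded expectations by default (Poisson draws behind a flag, seeded).
One realism caveat is deliberate: crude registered rates of 4–8 per
1,000 among adults 25+ are *low* relative to any stationary population
with realistic survival — in the real inputs this reflects incomplete
death registration (~89%) and a young, growing pyramid. Rescaling
hazards to those rates therefore yields implied district $e_0$ of
roughly 85–95 years. That is a property of registry-based baselines, not
a generator artifact, and it is what makes the resulting YLL and LLE
magnitudes line up with published provincial HIA values; but absolute
life expectancies from such schedules should not be read as estimates of
true survival.

*Exposure.* Each district receives a square grid (36 cells by default)
of concentrations equal to the district mean plus spatially
autocorrelated noise: seeded white noise smoothed by a separable
exponential kernel (correlation length 2 cells), centred so the district
mean is exact and truncated at zero. District means sit within ±1.5
μg/m³ of their province mean; province means span the configured range
endpoints exactly. Monthly-to-annual aggregation is an unweighted mean
of 12 months by default, with calendar-day weighting behind a flag, and
district aggregation of cells is an unweighted mean over member cells
(weights optional) — the simplest defensible readings where the
reporting conventions of such studies are silent.

What the synthetic data do *not* emulate: sex structure, migration,
within-band age detail, seasonality of exposure, or correlation between
pollution and mortality levels across districts. Passing tests therefore
demonstrate the correctness of the arithmetic and the stated invariants
under realistic magnitudes, not predictive validity for any real
province.

## Numerical and design choices

- Concentrations below a model's own support enter as $z = 0$ (HR = 1),
  never as negative excess.
- The policy counterfactual never modifies the GEMM curve; it enters
  only through the AF ratio.
- Interval arithmetic is exact (no resampling) unless `n_draws` is set;
  all random paths take explicit seeds and are reproducible
  byte-for-byte.
- Report tables round AD to integers and rates/YLL/LLE to one decimal;
  all internal computation is full precision.
- Problem sizes in the shipped tests and acceptance script — 33
  districts, 10⁶-person microsimulation cohorts, 25 random schedules —
  were chosen so a full run completes in well under a minute on a
  laptop while leaving Monte-Carlo error an order of magnitude below
  the asserted tolerances.

## Worked example

```{r example}
sim <- simulate_study_region(synthetic_config(seed = 1),
                             provinces = vietnam_provinces())
res <- run_hia(sim$demography, sim$districts, scenario("AQG", 5))
res$province[, c("unit_id", "ad", "ad_low", "ad_high", "ad_rate",
                 "lle_years")]
res$region[, c("ad", "ad_rate", "yll_rate", "lle_years")]
```

## Limitations

The pipeline consumes an exposure surface; it does not estimate one
(no satellite/AOD modelling). It covers the NCD+LRI GEMM outcome only,
not the five-cause split or IER/GBD curves, and mortality only — no
morbidity endpoints or economic valuation. Sex-stratified and projected
(cohort) life tables are out of scope, as is smoothing of observed
rates. Published provincial tables from registry-based HIAs cannot be
reproduced exactly without the underlying age-stratified counts; the
package instead guarantees the arithmetic identities and orderings those
tables must satisfy.
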