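---
title: "Methods: co-benefit valuation and equity assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-benefit valuation and equity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobenefits)
```

# What the package computes

The pipeline chains four analysis stages over census tracts:

1. **Exposure.** A gridded annual-mean PM2.5 field is aggregated to tracts
   through an explicit tract-to-cell weight table (`aggregate_to_tracts()`);
   scenario improvement is the per-tract reduction ΔC = reference −
   scenario, kept signed so local worsening is never clipped.
2. **Health impact.** Avoided deaths per tract follow the log-linear health
   impact function ΔY = Y₀·Pop·(1 − e^(−βΔC)). This is the form
   BenMAP-style assessments apply to long-term PM2.5 mortality
   concentration–response functions; for |βΔC| ≪ 1 it reduces to the
   linear Y₀·Pop·β·ΔC (the test suite checks agreement within 0.1% below
   |βΔC| < 10⁻³).
3. **Valuation.** Deaths are monetized at a VSL; the economy-wide scenario
   cost is split equally per capita and re-summed per tract, giving an
   implicit cost per life saved to compare against the VSL.
4. **Equity.** Benefits are ranked by tract vulnerability score and
   summarized by Lorenz curves, the Suits Index (statewide and per county),
   and a dispersity σ.

# Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| CRF β (two defaults) | per μg/m³ | ln(1.06)/10 = 0.0058269; ln(1.17)/10 = 0.0157004 | the two cohort relative risks conventionally used for long-term PM2.5 all-cause mortality; both overridable |
| CRF se | per μg/m³ | 9.63e−4; 5.45e−3 | back-derived from the cohorts' published 95% CIs (1.04–1.08, 1.05–1.30); the source analysis does not print the values it used, so these are explicit, overridable configuration |
| Pooling rule | — | `auto` | fixed effects unless Cochran's Q > χ²₀.₉₅(k−1), then DerSimonian–Laird random effects; mirrors "random and fixed effects" pooling without access to its internals. With the default CRFs, Q ≈ 3.19 < 3.84, so fixed effects is selected |
| VSL | USD/death (2018$) | 9.7e6 | standard federal-guidance value for this literature |
| DAC threshold | score | 75 | top quartile of the 0–100 vulnerability ranking |
| Net-benefit rule | — | cost/life **<** VSL | strict inequality; a tract exactly at the VSL does not qualify |

Pooling is done at the β level, once, and the pooled coefficient applied to
every tract; the alternative (pooling per-tract impacts computed with each
CRF) yields the same point estimates for a common pooled β but a different
uncertainty bookkeeping — the per-tract se here is the spread of the impact
function evaluated at β ± se (halved), a delta-method shortcut documented in
`impact_assessment()`, not a Monte Carlo.

# The Suits Index on discrete data

Tracts are sorted by ascending vulnerability score, with ties broken by
ascending `tract_id` — the ranking source is silent on ties and determinism
is required, so the tie-break is fixed and recorded in the run manifest.
The x axis is cumulative *population* fraction (not tract count). The
discrete Lorenz curve is piecewise linear; L is its trapezoid integral and
S = (0.5 − L)/0.5. The suite cross-checks the trapezoid rule against an
independent fine-grained Riemann sum to 10⁻⁶.

Choices where the method description was genuinely open:

* **Benefit units.** S is identical whether benefits are counted in
  deaths/yr or dollars/yr (they differ by the constant VSL), so the
  pipeline uses deaths/yr and does not offer a switch.
* **Negative benefits.** Tracts can worsen locally; their signed increments
  are retained so benefit totals are conserved. The [−1, 1] bound is then
  no longer guaranteed and results carry a `has_negative` flag.
* **County decomposition.** Population and benefit shares are renormalized
  within each county, so a county's S measures within-county progressivity
  only; a county can be negative while the statewide index is positive.
  Zero-benefit counties are reported with `NA` and a flag; a single-tract
  county is exactly 0 by construction.
* **Dispersity.** σ is the population (divisor n) standard deviation of the
  min–max-normalized benefits, unweighted; "0–1 normalized" admits other
  readings, and this one is scale-free and reduces to 0 for constant
  benefits by convention.
* **Population weighting.** Population-weighted means use tract-level
  population; net-benefit "population shares" weight tracts by population
  (i.e. they count people living in qualifying tracts).

# The synthetic world

`generate_region()` stands in for a chemical-transport-model grid, census
projections and a CalEnviroScreen-like ranking. Its defaults are a fixed
stated world, chosen once:

* 800 tracts in 10 counties on a 60×60 grid — roughly one tenth of a
  California-scale problem (~8000 tracts, 58 counties), small enough that
  the full pipeline runs in under a second.
* Tract populations log-normal(meanlog log 5000, sdlog 0.5): ~44M people
  over ~8000 tracts at full scale gives ≈5500 per tract, and a sdlog of 0.5
  reproduces the heavy right tail of real tract sizes.
* Incidence truncated-normal 0.008 ± 0.002 per person-year, floored at 10%
  of the mean (an all-cause mortality rate of the right magnitude, never
  zero or negative).
* Baseline field: mean 10.55 μg/m³ (the population-weighted baseline level
  the analysis context reports), spatial sd 2 μg/m³, floored at 0.
* Two default scenarios with mean reductions 0.68 and 0.59 μg/m³ and
  per-capita costs 10.6e9/44e6 and 15.8e9/44e6 USD per person-year. Costs
  are carried per capita because the equal-allocation method only ever uses
  the per-capita burden: pairing a full-scale total with a tenth-scale
  population would distort every cost-per-life by 10×. An explicit
  `total_cost` overrides this.
* Fields are smoothed white noise: Gaussian kernel, sd 5 cells, separable
  convolution with edge renormalization. A smoothed-noise field — not
  atmospheric physics — is the point: the generator emulates the spatial
  statistics (smooth, positively correlated with vulnerability where
  configured), not the chemistry.

**Vulnerability–benefit coupling.** A latent smoothed standardized field V
defines vulnerability: scores are the percentile ranks of tract-aggregated
V, rescaled to span exactly [0, 100] (so the top quartile, score ≥ 75, is
the DAC set). Each scenario's reduction field is
μ + σ·(wV + √(1−w²)G) with G an independent smoothed standardized field and
w = 2·sin(πρ/6) — the bivariate-normal coefficient whose Spearman
correlation equals ρ. Because scores are monotone in tract-aggregated V and
tract reductions are the same aggregation of the blended field, the rank
correlation between score and per-capita reduction approaches the
scenario's ρ (achieved ≈0.90 at ρ = 0.9 with 500 tracts). Coupling at the
field level, rather than reordering tract benefits after the fact, keeps
the stored grid exactly consistent with the tract values the pipeline
re-derives, and keeps reductions spatially smooth and concentrated in
high-vulnerability areas. One integer seed drives everything through fixed
per-stage sub-streams, so regions are bitwise reproducible.

**What a green test does not establish.** The generator reproduces the
*statistical shape* of the real problem — not transport physics, real
geographies, demographic composition, or the actual magnitudes of avoided
deaths, which at full scale depend on where concentration reductions
intersect population density. Headline physical results from the real
analysis are therefore out of reach at desk scale by design, and nothing in
the test suite claims them; the exactly re-derivable quantities are the
monetary identities (deaths × VSL, benefit − cost).

# Numerical choices

* Weight tables must sum to 1 per tract: 10⁻⁶ tolerance on input
  (external files), 10⁻⁹ for generator output.
* Cost allocation conserves the scenario total to 10⁻⁹ relative.
* Tracts with zero or negative avoided deaths get an infinite cost per
  life (never dropped), keeping population shares well-defined.
* Region files are written with 17 significant digits so read-back is
  bitwise exact; pipeline CSVs use 6 significant digits for readability and
  the summary JSON is unrounded. All writers are locale-independent, so
  reruns are byte-identical.
* `infer_beta()` inverts the aggregate impact function by monotone root
  bracketing (`uniroot`, tol 10⁻¹⁴); recovery of a known β is exact to
  well under 10⁻⁶ relative.
* Degenerate inputs: a 1×1 grid maps every tract to the single cell with
  weight 1; a spatially constant field standardizes to zero (scores then
  rank pure jitter); a single tract gets score 50.

# Known limitations

* No morbidity, ozone, or short-term effects; a single annual snapshot
  with no discounting.
* Uncertainty is propagated as ±1 se evaluation, not Monte Carlo, and no
  confidence intervals are attached to Suits Indices.
* The weight mapping is an input; no geometric overlay of real tract
  polygons is performed.
* Grid I/O is CSV only (no NetCDF reader is available in the supported
  dependency set).
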