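# cobenefits

Decarbonization policies that cut greenhouse-gas emissions also cut
co-emitted air pollutants, and the resulting PM2.5 improvements avoid
premature deaths. Two questions decide whether such a policy is also *just*:
how large are the health co-benefits relative to the mitigation cost, and
how are they distributed across communities with very different environmental
burdens? `cobenefits` is an R package for analysts who want to answer both at
census-tract resolution: it takes gridded annual-mean PM2.5 fields for a
reference and one or more mitigation scenarios, a tract table (population,
baseline mortality incidence, 0–100 vulnerability score), and economy-wide
scenario costs, and produces tract-level avoided mortality, monetized
benefits, implicit costs per life saved, and a Lorenz-curve /
Suits-Index equity assessment. A synthetic-region generator supplies
realistic desk-scale inputs so every stage is testable without any
atmospheric modelling output.

## The model

**Health impact.** Avoided all-cause deaths in a tract follow the standard
log-linear health impact function

ΔY = Y₀ · Pop · (1 − e^(−β·ΔC))

with Y₀ the baseline incidence (per person-year), Pop the tract population,
ΔC the annual-mean PM2.5 reduction (μg/m³, positive = improvement) and β the
log-relative-risk coefficient per μg/m³. Default coefficients are the two
cohort estimates conventionally applied to long-term PM2.5 mortality
(RR 1.06 and RR 1.17 per 10 μg/m³), combined by inverse-variance pooling:
fixed effects, DerSimonian–Laird random effects, or an automatic rule that
switches to random effects when Cochran's Q exceeds the χ²₀.₉₅(k−1)
threshold. All coefficients and standard errors are configuration, not
constants.

**Valuation.** Avoided deaths are monetized at a value of a statistical life
(default $9.7M, 2018$). The scenario's economy-wide cost is allocated
equally per capita; a tract's implicit cost per life saved is its allocated
cost divided by its avoided deaths, and the tract shows a *net benefit* when
that ratio is strictly below the VSL.

**Equity.** Tracts are ranked by vulnerability score; the Lorenz curve
accumulates population share (x) against benefit share (y), and the Suits
Index is S = (K − L)/K with K = ½ and L the trapezoid area under the curve.
S ∈ [−1, 1] for nonnegative benefits: 0 means proportional, positive means
benefits favor disadvantaged communities (score ≥ 75 = top-quartile DAC),
negative the opposite. County-level indices renormalize within each county.
A dispersity statistic σ (the standard deviation of the min–max-normalized
tract benefits) summarizes how uneven the distribution is.

## Worked example

```r
library(cobenefits)
bundle <- run_demo(seed = 1, outdir = "demo_out", n_tracts = 800)
```

prints (computed output, seed 1):

```
Demo region: 800 tracts, 200 DAC tracts, population 4.45e+06
  building electrification: 147.8 avoided deaths/yr, S = 0.1056, net $3.6e+08/yr
  truck electrification:    126.6 avoided deaths/yr, S = 0.2446, net $-3.72e+08/yr
  Tradeoff: the scenario with the larger total benefit allocates them
  less progressively toward disadvantaged communities (smaller Suits Index).
```

Reading this: the demo builds a 4.45-million-person synthetic region with two
mitigation scenarios. The first was generated with the larger mean PM2.5
reduction (population-weighted 0.687 μg/m³ here), so it avoids more deaths
(147.8/yr vs 126.6/yr); the second was generated with the stronger coupling
between vulnerability and benefit, so its Suits Index is higher (0.245 vs
0.106) — its benefits flow disproportionately to disadvantaged tracts. That
benefit-size-versus-progressivity tradeoff is exactly the pattern this kind
of analysis is designed to expose. `demo_out/` then contains, per scenario,
the tract impact and valuation CSVs, county Suits tables, Lorenz curve
points, a per-county comparison (`delta_avoided_deaths`, `delta_suits`), an
unrounded `summary.json` and a run manifest with the config hash and every
default actually used.

The same pipeline runs on your own inputs via a JSON config:

```r
bundle <- run_pipeline("config.json", "out")
```

or from the shell:

```sh
Rscript inst/cli/cobenefits.R demo --seed 1 --out demo_out
Rscript inst/cli/cobenefits.R run  --config config.json --out out
```

## Scope

The package deliberately stops at the analysis layer: emissions processing,
chemical-transport modelling (the source of real concentration fields),
morbidity endpoints, ozone effects, and demographic attribution are out of
scope. Grids are read as plain CSV (`row,col,value`, 0-based row-major
indices). See `vignettes/methods.Rmd` for the modelling choices, synthetic
world, and limitations.
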