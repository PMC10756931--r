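---
title: "Estimating community water system fluoride exposure and county-level inequalities"
author: "cwsfluoride"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating community water system fluoride exposure and county-level inequalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwsfluoride)
```

## The problem

Community water systems (CWSs) — public systems serving the same population
year-round — are the main route of drinking-water fluoride exposure in the
United States. Fluoride reaches tap water both geogenically (groundwater in
contact with fluoride-bearing rock) and through manual fluoridation toward
the 700 µg/L optimal level for caries prevention. Chronic exposure above the
WHO guideline (1500 µg/L) or the EPA maximum contaminant level (4000 µg/L)
is a health concern, and exposure is not distributed evenly: small systems,
groundwater-reliant regions, and counties with particular sociodemographic
profiles can carry systematically higher concentrations.

`cwsfluoride` implements the full analytic chain for this question:

1. **CWS estimates** — convert raw compliance monitoring records into
   per-system chronic (multi-year) average concentrations;
2. **Subgroup inequalities** — distributional summaries and exceedance
   counts across system subgroups, compared with Kruskal–Wallis tests;
3. **County aggregation** — population-weighted county mean / 90th / 95th
   percentile concentrations with a coverage filter;
4. **Spatial inference** — Moran's I, Lagrange-multiplier diagnostics, and
   maximum-likelihood spatial error models of log county fluoride on county
   racial/ethnic composition, reported as geometric mean ratios (GMRs) per
   10 percentage-point higher composition;
5. **Synthetic data** — a generator that emulates all four inputs with
   planted parameters, so every stage can be tested end to end including
   parameter recovery.

## From monitoring records to CWS estimates

A monitoring record carries a system id, date, concentration with units
(mg/L or µg/L), a record-specific limit of detection (LOD), a detect flag,
and a treated/raw flag. Estimation proceeds as:

* **Unit standardization.** All values and LODs are converted to µg/L
  (mg/L × 1000). Unrecognized unit strings are an error, not a guess.
* **Nondetect substitution.** Left-censored records receive LOD/√2, the
  standard substitution for compliance data when the censored fraction is
  moderate. A nondetect without a usable LOD cannot be imputed and is
  dropped, with the count reported in the QC log. Substitution keeps every
  estimate strictly positive (LOD/√2 > 0), which the log-scale county models
  require.
* **Yearly averaging with the treated/raw rule.** The default yearly value
  is the arithmetic mean of all samples in the calendar year, weighting
  treated and raw samples equally. When both exist and the raw mean exceeds
  the treated mean, the year uses treated samples only — the water actually
  distributed to consumers. A year with only raw samples keeps the raw mean:
  the rule is an override of raw-dominated averages, and with no treated
  comparator there is nothing to override. The override can only lower a
  yearly mean, never raise it (a tested invariant).
* **Chronic average.** The unweighted mean of yearly averages inside the
  configured window (default 2006–2011). Records outside the window are
  dropped and counted; a system with no in-window year is omitted and
  counted.

QC accounting (dropped records, rejected nondetects, excluded counties,
islands) is a first-class output, because the N-accounting of an exposure
assessment is part of its result.

### Subgroup summaries

Per subgroup (source water type, EPA size category `≤500 / 501–3300 /
3301–10,000 / >10,000`, region, sociodemographic cluster, correctional,
fluoridation): the mean with a normal-approximation 95% CI
(mean ± 1.96·SD/√n — standard at these group sizes), empirical 90th/95th
percentiles with linear interpolation between order statistics, and counts
of systems strictly above each threshold (700/1500/4000 µg/L by default;
strict `>` matches the tabulated convention and is configurable). Percents
are reported half-even at one decimal. Systems serving counties assigned to
different sociodemographic clusters appear once per cluster in the cluster
analysis; all other groupings deduplicate to one row per system.
Kruskal–Wallis tests use mid-rank ties correction; an all-identical input
returns H = 0, p = 1 rather than an undefined ratio.

## Population-weighted county aggregation

Within a county, each system's weight is its population served divided by
the total served by all systems serving that county. The county mean is the
weighted mean; the 90th/95th percentiles use the cumulative-weight rule —
sort ascending, take the smallest value whose cumulative weight reaches q.
This estimator is deterministic, order-invariant, monotone in q, and matches
the intuition of replicating each system in proportion to its weight; an
interpolating variant sits behind `method = "interpolate"`. Counties whose
monitored systems cover less than 50% of the public-water-reliant population
are marked `inadequate` (exactly 50% is kept — "less than fifty percent" is
what is excluded); counties with no monitored systems at all are `no_data`,
a distinct category. Multi-county systems contribute their full population
served to each county they serve; how such populations should be
apportioned across counties is genuinely unknown upstream, so the package
mirrors the duplication convention rather than inventing shares. Missing
fluoridation flags count as not-fluoridated (voluntary reporting is
incomplete) and are tallied.

## Spatial inference

**Weights.** Queen contiguity (neighbours share any boundary point,
including corners) gives a binary symmetric matrix with zero diagonal. All
statistics use the row-standardized form W: row standardization is the
spatial-econometrics default, makes Moran's I a regression-type coefficient,
and gives the eigenvalue-bounded feasible interval for the spatial
parameter; the binary matrix is retained on the object. Counties with no
neighbours (islands, possibly created by filters) are excluded from spatial
fits with a logged count.

**Moran's I** is `(n/S0)·z'Wz / z'z` on demeaned values. The package reports
the expectation −1/(n−1), a z-score and p-value under the normal
approximation (normality assumption), and a seeded permutation p-value from
random relabelings (999 by default). By default it is computed on the
untransformed county weighted mean; a log-scale flag is available, and the
two agree in direction because Moran's I is invariant to positive affine
transforms (tested property).

**LM diagnostics.** From the OLS residuals e:
`LM_err = (e'We / s²)² / T` with `T = tr(W'W + WW)`, and the standard
(non-robust) LM-lag form with the projected spatial lag of the fitted
values. Both refer to χ²(1). The diagnostics guide model choice; the spatial
error model is the default continuation, with the choice exposed as
configuration rather than hard-coded.

**Spatial error model (ML).** The model is `y = Xβ + u`, `u = λWu + ε`. For
fixed λ the spatially filtered regression `(y − λWy) ~ (X − λWX)` is solved
by least squares; the concentrated log-likelihood adds the Jacobian
`ln|I − λW| = Σ ln(1 − λω_i)` computed from the eigenvalues of W (real,
obtained from the similar symmetric matrix `D^{-1/2} B D^{-1/2}` and cached
across fits on the same weights). λ is maximized by bounded 1-D search on
the eigenvalue interval with tolerance 1e-8. Standard errors come from the
observed information (numerical Hessian of the full likelihood at the
optimum), falling back on the exact GLS covariance for β — valid because β
is information-orthogonal to (λ, σ²) in this model. At λ = 0 the model
reduces exactly to OLS (tested to 1e-10), and `loglik(λ̂) ≥ loglik(0)` is
guaranteed by construction.

**Reporting.** With log outcome and composition entered as percent/10, the
GMR per 10 percentage points is `exp(β)` with CI `exp(β ± 1.96·SE)`; the
percent change is `100·(GMR − 1)`, rounded to integer percent for reports.
Model 1 adjusts for percent groundwater, population density (per 1000
persons/sq mi) and the socioeconomic vulnerability index; Model 2 adds the
population-weighted percent of public water reported fluoridated. When that
covariate is constant (e.g. zero everywhere in a fluoridation-free
scenario), it is dropped and Model 2 equals Model 1 by construction.
Analyses restrict to counties with at least 100 residents of the group of
interest (positivity), so each group has its own analysis n. The
majority-community sensitivity rescales composition to 60-point units; the
upper-tail sensitivity swaps the outcome to the weighted 95th percentile.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* counties on an `r × c` rectangular grid with queen adjacency (the lattice
  stand-in reproduces the full contiguity machinery without shapefiles);
* county covariates from spatially autocorrelated logit-normal fields —
  composition percentages, density, SVI, percent groundwater — so that
  covariates themselves carry spatial structure, as real demographics do;
* a latent log-fluoride surface `Xβ + u` with simultaneous-autoregressive
  errors `u = λWu + ε` realized by solving the sparse linear system;
* a system inventory whose systems partition the covered share of each
  county's public-water population in log-uniform relative sizes, with
  source type, region/cluster labels, tribal/correctional flags, and
  voluntary fluoridation reporting (24% fluoridated among the 79% with
  data);
* monitoring records per compliance window (yearly for surface systems),
  log-normal around the system mean, with raw samples biased upward ×1.1 so
  the treated/raw rule engages, a 50/50 mg/L–µg/L unit mix, and left
  censoring at the record LOD;
* a truth record (`beta_true`, `lambda_true`, `gmr_true_per_10pct`, county
  latent means) for recovery testing.

One integer seed drives everything; per-table substreams are derived
deterministically, so identical configurations give identical tables.

### Calibration of the defaults

Defaults are chosen once, as study conditions:

* `sigma_spatial = 0.6`, `sigma_cws = 0.15`, `sigma_record = 0.15` put the
  county-level log spread near 0.7–0.8, consistent with a county
  concentration distribution whose standard deviation is about equal to its
  mean (coefficient of variation ≈ 1), and keep the spatial signal dominant
  over aggregation noise;
* `lod_ug_l = 410` is the empirical 30th percentile of record values under
  the default configuration, so roughly 30% of records are nondetect —
  matching the censored fraction typical of fluoride compliance data
  (about 70% detected);
* `frac_low_coverage = 0.15` yields a coverage-filter exclusion rate near
  the ~15% seen in practice;
* fluoridated systems (24% of reporters) have their latent mean raised to at
  least log(700), clustering them near the optimal level;
* planted effects: GMR 1.15 per 10% Hispanic/Latino, λ = 0.5, plus small
  groundwater and SVI effects.

### What the generator does *not* emulate

Real county topology and island counties; state-by-state reporting gaps
beyond the per-county coverage knob; geochemical drivers (well depth, pH);
the extreme skew of the real system-size distribution (a log-uniform range
keeps county aggregates informative at a few hundred counties); selling /
purchasing relationships behind adjusted populations served. Passing tests
therefore demonstrate that the *machinery* is correct under the stated
generative model — not that real-data results are reproduced.

## The recovery benchmark

The acceptance suite reruns the complete pipeline over 50 seeded replicates
and asks whether the planted GMR lies inside the fitted 95% CI at least 90%
of the time and whether the mean λ̂ lands within 0.5 ± 0.05. The benchmark
configuration deviates from the defaults in three ways, each an
estimand-alignment choice, not a convenience:

* **No fluoridation intervention** (`frac_fluoridated = 0`). The planted
  coefficient describes *geogenic* fluoride. Raising a quarter of systems to
  a 700 µg/L set-point is an intervention uncorrelated with composition; it
  redefines the county-level estimand away from the planted parameter, so a
  recovery experiment with the intervention active would test the wrong
  null. The intervention machinery is exercised by its own tests and by the
  default-configuration run.
* **Light censoring** (`lod_ug_l = 150`). LOD/√2 substitution is
  approximately unbiased only when the censored fraction is modest; under
  heavy censoring the common substituted value compresses the low end of the
  county distribution and biases both the composition coefficient and λ̂
  toward the null. This attenuation is a real property of the substitution
  estimator — the benchmark is designed so it does not confound parameter
  recovery.
* **Full coverage** (`frac_low_coverage = 0`). Coverage dropout perforates
  the lattice; a subset of a simultaneous-autoregressive field is not itself
  SAR with the same λ, so holes attenuate λ̂ for reasons unrelated to the
  estimator.

The acceptance script reports the realized coverage percentage, mean
estimated GMR, and mean λ̂ each run.

## Numerical choices and degenerate inputs

* λ optimizer: bounded golden-section/parabolic search, tolerance 1e-8;
  estimates within 1e-4 of an interval endpoint set a convergence warning.
* Eigenvalues of W are computed once per weights object and reusable across
  fits (`eigenvalues =` argument).
* Weighted-quantile cumulative comparisons use a 1e-12 slack so exact
  cumulative weights (0.9 at q = 0.90) are kept on the boundary.
* Degenerate inputs: constant values are an error for Moran's I (the
  statistic is 0/0), H = 0 / p = 1 for Kruskal–Wallis; a constant Model-2
  fluoridation covariate is dropped; islands are an error for spatial
  statistics unless excluded first.
* Percent reporting is half-even at one decimal; concentrations in report
  tables are full precision in CSVs and rounded only for display.

## Problem sizes used by the test-suite

Unit fixtures use 4–50 spatial units so dense brute-force oracles (plain
matrix arithmetic, `determinant()`) can verify Moran's I, both LM
statistics, and the eigenvalue log-determinant to 1e-8. Type-I error checks
use 1000 null replicates on a 15×15 lattice (199 permutations each for the
Moran test). The recovery benchmark uses 50 replicates of the 20×20-county
default scale — about 14,000 records and 4,900 systems per replicate. These
sizes were chosen so the full suite completes in a few minutes while keeping
Monte-Carlo error well inside the asserted bands.

## Known limitations

* The LOD/√2 substitution is the conventional, not the optimal, treatment
  of left-censoring; likelihood-based censored estimators would reduce the
  attenuation described above and are out of scope.
* Spline dose-response and region-stratified models are not implemented;
  the model set is Models 1–2 with the scale/outcome sensitivity switches.
* Multi-county population apportionment follows the duplication convention
  and therefore double-counts populations when systems span counties.
* Choropleth rendering is out of scope; county estimates are exported as
  CSV with an explicit `included / inadequate / no_data` status column.
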