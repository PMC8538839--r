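---
title: "Methods: exposure assignment, methylation scores, and the calibrated generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure assignment, methylation scores, and the calibrated generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `methylscore` implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-cohort generator does and does not
emulate.

## Scientific setting

Prenatal exposure to particulate matter (PM2.5, PM10) has reproducible DNA
methylation associations in cord blood. Whether those signatures persist
into childhood, and whether weights learned in blood transfer to saliva, is
the question this pipeline operationalizes: assign windowed prenatal
exposure from monitor networks, compute cumulative DNA methylation scores in
childhood saliva using cord-blood EWAS weights, and test score–exposure
associations with covariate adjustment and repeated-measures models. The
motivating cohort data are restricted, so the package ships a calibrated
synthetic cohort generator that reproduces the statistical structure the
analysis assumes and plants known effects for validation.

## Exposure assignment

Daily concentration at a residence is the inverse-distance-weighted mean
over monitors within a search radius:

$$\hat c(s, d) = \frac{\sum_k x_{kd}/d_k}{\sum_k 1/d_k},$$

with $d_k$ the haversine distance (mean Earth radius 6371.0088 km) from the
residence to monitor $k$. Parameters and their defaults:

* `radius_km = 60` — monitors at distance $\le$ 60 km contribute (inclusive
  boundary; the field convention the package follows states the radius
  without specifying strictness, and inclusivity avoids dropping a monitor
  sitting exactly on the circle).
* inverse-distance power 1 — "inverse distance", not inverse-square.
* zero-distance rule — a monitor coinciding with the residence returns its
  value (the average of coincident monitors), the $d \to 0$ limit of the
  weighted mean.
* `window_days = 91` — "three months before" an anchor date is implemented
  as the 91 days ending the day before the anchor (half-open; the anchor day
  itself is excluded). Month arithmetic is otherwise ill-defined across
  calendars.
* `min_coverage = 0.75` — days with no in-radius reading are omitted from
  the window mean; when fewer than 75% of window days are covered the
  estimate is marked missing with reason `"insufficient coverage"` rather
  than silently averaging a sparse window. The source procedure is silent on
  missing monitor-days; 0.75 is configurable.

Whether monitor eligibility should be evaluated per day or once per
residence is likewise unstated in the source procedure; the package
evaluates it daily (a monitor missing a reading simply contributes nothing
that day), which is the natural consequence of computing daily IDW first.

A no-coverage day yields an `NA` signal with an explicit reason, never a
zero: zero is a valid concentration.

## Quality control

Sample filters, applied in order with first-match attribution:

1. detection: fraction of sites with detection $p > 0.01$ strictly greater
   than 10% (a sample at exactly 10% is kept — the rule's wording is a
   strict inequality);
2. sex discordance: predicted sex differs from recorded sex (the predicted
   sex is consumed as a precomputed feature; re-implementing array sex
   calling is out of scope);
3. abnormal sex-chromosome intensity: feature outside a configurable band
   (default [−4, 4]). No quantitative definition of "abnormal" exists in
   the source procedure, so the generator labels the feature and the filter
   applies a band.

Probe filters: detection $p > 0.01$ in $\ge$ 5% of post-sample-QC samples
(the fraction threshold read as inclusive; the source wording "in 5% of
samples" is ambiguous and inclusivity is the conservative reading), plus a
user-supplied cross-reactive blocklist. Both filters are idempotent, and
blocklist ids absent from the matrix warn rather than error.

Cell composition: saliva is modelled as a two-cell-type mixture
(immune/epithelial). For a reference panel $R \in [0,1]^{m \times 2}$ and a
sample $\beta$, the package solves

$$\min_{p \in [0,1]} \lVert \beta - pR_\mathrm{imm} - (1-p)R_\mathrm{epi}
\rVert^2,$$

whose solution is the projection of $\beta - R_\mathrm{epi}$ onto
$R_\mathrm{imm} - R_\mathrm{epi}$, clamped to $[0,1]$ — the exact
constrained least-squares solution for two classes, requiring no iterative
solver. Collinear reference columns raise an error naming the condition
number. The published childhood saliva reference panel itself is not
redistributed; the generator emits a synthetic panel with the same shape.

## Cumulative DNA methylation scores

$$S_i = \sum_j w_j \, t(\beta_{ij}),$$

with $t$ the per-site z-score (`"zscored"`, primary), identity (`"raw"`),
or per-site mean-centering (`"centered"`), and weights $w_j$ from an
independent cord-blood EWAS meta-analysis. Site statistics and the final
z-score standardization are computed over the standardization population —
by default all QC-passing observations pooled across visits (the source
procedure standardizes "within the study sample" without specifying
pooling; per-visit standardization is available by scoring each visit's
matrix separately). Two consequences the test suite asserts:

* per-site mean-centering shifts every participant's sum by the same
  constant, so the standardized `"raw"` and `"centered"` scores are
  identical to numerical precision — which is why report tables show
  duplicated columns for these variants;
* rescaling all weights by a constant leaves standardized scores unchanged.

Missing weight-table sites are dropped with a warning and recorded in
`n_sites_used`; weights are deliberately not renormalized, preserving the
semantics of the published effect estimates at the cost of comparability,
which the log makes visible.

## Association models

Visit-stratified models are OLS; all-visit models are linear mixed models
with a per-participant random intercept, fitted by REML in `nlme` (the
estimator the motivating analysis used; ML yields nearly identical fixed
effects here). Fixed-effect intervals are Wald z intervals for the mixed
model (the reference degrees-of-freedom method being unstated in the source
procedure) and t intervals for OLS. The exposure coefficient is reported
per interquartile-range increase: the regressor is `exposure / IQR`, so
`effect_per_IQR = per-unit coefficient x IQR` holds exactly. The IQR is
the analytic subsample's by default, or a fixed reference constant
(10.73 µg/m³/day for PM2.5, 3.20 for PM10 — the published cohort values)
for exact comparability across strata; the acceptance computations use the
fixed constants.

The adjustment set is child sex, age at measurement, maternal
race/ethnicity (reference level: largest category), income-to-needs ratio,
marital status (reference: married), and the immune cell proportion. The
motivating analysis adjusts for both immune and epithelial proportions;
under the two-type sum-to-one deconvolution used here they are exactly
collinear, so the model includes only the immune proportion — an
equivalent parameterization. Rank deficiency raises an error listing the
aliased terms rather than silently dropping them. Complete cases only; no
multiple-testing correction, matching the reporting it mirrors.

When no participant has repeated measures the random intercept is
unidentifiable; `fit_mixed_model()` then fits OLS and flags the result
(`lm_degenerate_mixed`), and the test suite asserts the mixed model
reproduces OLS in that limit to 1e-6.

The sensitivity suite refits with co-pollutant adjustment, postnatal
(age-1, age-3) exposure adjustment, the NO2 score as outcome (specificity),
and per-CpG percent-methylation outcomes at the six published PM10 sites;
analyses with missing inputs are skipped with a log entry.

## The synthetic cohort generator

The generator's defaults are the study conditions the package emulates.

**Exposures.** Margins are truncated normal — mean 27.9, sd 7.04, range
[14.3, 45.0] µg/m³/day for PM2.5; mean 15.0, sd 3.06, range [7.5, 20.2]
for PM10 — with parent parameters solved numerically so the *truncated*
distribution hits the target moments. Dependence uses a gaussian copula;
each pairwise latent correlation is solved by 48-point Gauss–Hermite
quadrature so the *realized* Pearson correlation matches its target
(prenatal–age-1: 0.54 PM2.5, 0.71 PM10; prenatal–age-3: 0.57, 0.69;
cross-pollutant same anchor: 0.20). The age-1–age-3 correlations (0.65,
0.75) and cross-pollutant cross-anchor value (0.12) are unreported in the
emulated cohort and are generator choices consistent with the reported
pairs. Infeasible (non-positive-definite) target or latent matrices raise
an error naming the block. The marginal family itself is a choice — only
mean, sd and range are reported — and truncated normal honors all three.

**Score-CpG betas.** For pollutant $p$ with weights $w_j$, site baselines
$\mu_j$, site sds $\sigma_j$, signal fraction $f$ (default 0.3) and planted
slope $b$ (SD of standardized score per `iqr_ref` of exposure):

$$\beta_{ijv} = \mu_j + f\sigma_j\,\mathrm{sign}(w_j)\,S_{iv}
  + \sigma_j\sqrt{1-f^2}\,\varepsilon_{ijv},$$

where the latent score $S_{iv} = b'\tilde x_i + \text{noise}$ has unit
variance, $\tilde x$ is exposure centered and scaled by `iqr_ref`, and both
the latent score and the site noise carry the configured visit-to-visit
correlation $r_s$ (0.55 PM2.5, 0.22 PM10, 0.45 NO2). Because the z-scored
weighted sum then equals $\lambda S + N$ with $\lambda = f\sum_j |w_j|$ and
$\mathrm{Var}(N) = (1-f^2)\sum_j w_j^2$, setting
$b' = b\sqrt{\lambda^2 + \mathrm{Var}(N)}/\lambda$ makes the realized
standardized score carry slope exactly $b$ in population, and the realized
between-visit score correlation equal exactly $r_s$. Two deliberate
calibration choices follow from this construction:

* score-site betas are linear-gaussian (clamped to [0,1]; baselines sit far
  enough from the bounds that clamping is measure-zero at the defaults)
  rather than logit-normal — a logit link would distort the planted slope
  the validation targets measure. Background CpGs keep the logit-normal
  bimodal construction that real array betas exhibit;
* score-site sds sit in a narrow band (0.012–0.018): with strongly
  heterogeneous site sds and independent site noise, the raw-variant score
  is dominated by the highest-variance site and decorrelates from the
  z-scored variant below the 0.79 floor observed in real data and asserted
  by the tests. Site means for the six PM10 CpGs follow their published
  summaries.

The construction implies a feasibility constraint $r_s \ge b'^2
\mathrm{Var}(\tilde x)$ — a between-visit score correlation cannot fall
below the variance share of the (visit-constant) prenatal exposure signal —
and the generator errors explicitly when a configuration violates it.
Default planted slopes are −0.029 (PM2.5), −0.024 (PM10) and 0 (NO2, a
specificity null).

**Everything else.** Covariates are drawn with frequencies matching the
emulated cohort (50.5% male; 56.3/16.6/19.8% NH Black/NH White/Hispanic;
23.7% married; log-normal income-to-needs with median 1.4; visit ages
9.30 (0.34) and 15.4 (0.49)). Immune fractions are Beta-distributed with
per-visit means 0.953/0.925. Detection p-values are Uniform(0, 0.005) for
good calls; planted detection failures redraw 15% of a sample's sites from
Uniform(0.02, 1), making threshold crossings unambiguous. Fault injection
is count-exact (sampling without replacement, disjoint across rules), so QC
tests are deterministic. Monitors, when generated, are co-located with each
participant's residence and their daily window values average exactly to
the assigned exposure, so the IDW stage reproduces the calibrated exposures
through the real code path; multi-monitor interpolation behavior is
exercised by unit tests with hand-built networks.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatial realism of a 20-city monitor network
(each participant has a dedicated co-located monitor), IDAT-level intensity
noise and normalization artifacts (betas are treated as post-normalization),
probe-type chemistry differences, batch effects, genetic structure,
population stratification correlated with exposure, and any real
cross-reactive probe content (the blocklist is user-supplied). The
within-person correlation of background CpGs (default 0.4) is a plausible
choice, not an estimate.

## Numerical choices and degenerate inputs

* Truncated-normal moment matching: Nelder–Mead on squared moment error,
  tolerance 1e-14, errors if the residual exceeds 1e-8.
* Copula calibration: `uniroot` on the quadrature-realized correlation,
  tolerance 1e-9.
* Deconvolution: closed form; collinearity guard at condition number 1e8.
* Scores: zero-variance sites are dropped with a warning under `"zscored"`;
  an all-constant matrix errors (the score is undefined); a zero-variance
  score errors at standardization rather than dividing by zero.
* Median splits send ties to the lower stratum; degenerate strata return
  `NA` with a reason rather than failing the whole test table.
* `fisher.test` falls back to simulation (B = 10,000) when the exact
  network exceeds its workspace.
* Mixed-model non-convergence propagates as an error pointing at
  `nlme::lmeControl`.

## Problem sizes

The test suite and the reproduction script choose sizes that mirror the
emulated study where that matters and stay small elsewhere: exposure
calibration at n = 10,000 draws; between-visit score correlations on 747
paired participants averaged over replicate cohorts; effect recovery over
200 replicates of n = 735 age-15 observations (the emulated age-15 analytic
sample size); QC count fidelity on a 1,811-observation fixture with planted
43/20/3 faults; null coverage and type-I error over 500 simulations of
small cohorts. Tolerances for stochastic checks are three Monte-Carlo
standard errors of the quantity as computed.

## Known limitations

* Two cell types only; saliva heterogeneity beyond immune/epithelial (and
  any multi-class Houseman-style deconvolution) is out of scope.
* The PM2.5 and NO2 weight tables are synthetic placeholders; only the PM10
  table carries published weights, so cross-pollutant comparisons on
  synthetic data say nothing about real cross-pollutant biology.
* Exposure assignment ignores residential mobility within the window,
  indoor/outdoor infiltration and seasonality confounding — the same
  limitations the motivating design carries.
* The survey's unmarried-mother oversample is reflected in covariate
  frequencies but not modelled with survey weights.
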