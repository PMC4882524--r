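---
title: "Latent-variable path models for foliar nitrogen: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable path models for foliar nitrogen: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foliarsem)
```

## The scientific problem

Leaf nitrogen can be expressed per unit dry mass (Nmass, mg g⁻¹) or per
unit leaf area (Narea, g m⁻²; Narea = Nmass·LDW/LS). Across a broad
climate and soil gradient, both quantities respond to mean annual
precipitation (MAP) and temperature (MAT), to topsoil nitrogen, phosphorus
and potassium (TSN, TSP, TSK), and to leaf morphology — specific leaf area
(SLA), leaf size (LS) and leaf dry weight (LDW). Because these drivers act
on each other as well as on leaf nitrogen (precipitation leaches soil
nutrients; soil phosphorus shifts morphology; morphology concentrates or
dilutes nitrogen), bivariate correlations conflate routes of influence.
The package implements the standard remedy: a recursive structural
equation model (SEM) in which morphology enters as a latent factor (LMT)
measured by two indicators, fitted by maximum likelihood to the sample
moment matrix, followed by decomposition of every predictor's influence
into direct and mediated components and by an exact partition of each
variable's explained variance.

The study system ships with the package: `table2_fixture()` is the
published 10-variable Pearson correlation matrix over 90 oak trees —
the sufficient statistic for every fit — and `paper_models()` holds the
two published final topologies plus a reconstructed full prior model.

## Model and estimation

A model is a set of directed paths among structural variables, latent
definitions `L =~ ind1 + ind2 (+ ind3)`, and free residual covariances
(`foliarsem`'s text grammar: `path X -> Y`, `latent L: A B`,
`cov X ~~ Y`). In reticular (RAM) form the implied covariance over the
observed variables is

    Sigma(theta) = F (I - A)^(-1) S (I - A)^(-T) F',

with `A` holding paths and loadings, `S` variances and free covariances,
and `F` the observed-row filter. Estimation minimizes the ML discrepancy

    F_ML = ln|Sigma| - ln|S| + tr(S Sigma^(-1)) - p,

and `(n-1)·F_min` is the model chi-square; `df = p(p+1)/2 - t` with `t`
free parameters. Each latent's scale is set by fixing its first
indicator's loading to 1; reported solutions are standardized, where that
choice is immaterial, and each latent's sign is normalized so its first
(SLA) loading is positive.

Numerical choices, all defaults of `fit_ml()`:

* quasi-Newton optimization (`nlminb`) with an analytic gradient;
  variances log-transformed, bounded below at 1e-6; convergence declared
  at projected-gradient norm < 1e-6 (the projection handles boundary —
  Heywood — solutions, which are flagged);
* 5 restarts, the first from deterministic starts (paths 0, loadings 1,
  variances at half the sample variance of the mapped variable — 0.5 on
  correlation input), the rest perturbed under a fixed seed (default
  26845); the best objective is kept, then polished with L-BFGS-B when the
  gradient norm still exceeds the tolerance;
* standard errors from the central-difference Hessian (step 1e-5, on the
  transformed scale) via `cov(theta) = 2/(n-1) · H^(-1)`; bound-active
  variances are treated as fixed when inverting (their SE is undefined at
  the boundary);
* fit indices: RMSEA, GFI/AGFI, CFI against the closed-form independence
  baseline (`F_b = -ln|R|`), and AIC in the `chisq + 2t` convention.
  RMSEA and AGFI are reported as `NA` at df = 0 rather than extrapolated.

**Correlation input.** The published analysis fit raw data; only the
rounded correlation matrix is printed. The package therefore treats a
correlation matrix as a covariance matrix, which reproduces every
standardized quantity but makes standard errors approximate: sample
correlations fluctuate less than covariances, so Wishart-based SEs
overstate the spread of scale-sensitive parameters (loadings) on
correlation input. The validation driver (`analysis/05_parameter_recovery.R`)
therefore calibrates SEs on simulated *covariance* input, where the theory
applies; there the replicate SD/SE ratios sit within 10% of 1 at n = 90
and the mean standardized-parameter bias stays ~0.01.

## Effects and variance partitioning

On the standardized system `A*`, total effects are `(I - A*)^(-1) - I`;
direct effects are `A*`; indirect effects the difference — an exact
identity, cross-checked in the tests against brute-force enumeration of
simple directed chains. Composite (indirect/total) effects carry no
recomputed significance; stars attach to direct paths only, since the
published table states no delta-method or bootstrap procedure.

The variance partition writes each variable as a linear combination of
independent source shocks (exogenous variables and disturbances) via
`(I - A*)^(-1)`. The contribution of a group of shocks to a response is
the quadratic form of the response's row with the shock covariance
restricted to the group; within-group covariances (the correlated TSK/TSP
residuals, pooled into one "TSK and TSP" column) stay inside the group's
share, while covariances *across* groups would break additivity and are
rejected. Shares are exact: over all groups plus the response's own
disturbance they sum to 100%, so group shares sum to `100·R²`. The source
literature cites an external partitioning method without formulas; the
orthogonal-shock decomposition is this package's interpretation, adopted
because it is exact and reproduces the published partition table from the
published effect sizes.

## Backward model search

`stepwise_prune()` starts from the full prior and repeatedly drops the
structural path or free covariance whose removal most lowers AIC,
stopping when no drop helps; ties break lexicographically and candidate
fits are warm-started, so the search is deterministic given moments and
seed. Loadings are never dropped — indicator choice is treated as part of
the model statement, not searched, because the published record selects
different indicator pairs for the two outcomes without describing an
indicator-level procedure.

Two housekeeping rules remove variables, shrinking the moment matrix and
refitting (such steps are flagged as not AIC-comparable): a variable with
no incident edge at all, and — the package's design extension — a
non-outcome variable left with no directed route to the outcome. The
extension matters: AIC retains any edge whose removal costs more than two
chi-square units (roughly p < 0.16), so a strongly precipitation-driven
soil variable that no longer influences leaf nitrogen would otherwise sit
in the model forever as an explanatorily inert sink, while the study's
stated criterion for exclusion was precisely the absence of a direct or
indirect effect on the outcome.

An optional post-AIC stage (`alpha = 0.05`) eliminates remaining
insignificant edges one at a time, mirroring the convention that published
path diagrams carry only significant arrows. It is off by default: the
reconstructed prior's three-indicator latent is sign-inconsistent with the
printed correlations (r(SLA,LS) = 0.35, r(SLA,LDW) = −0.37,
r(LS,LDW) = 0.69 imply a negative squared loading), which forces a
Heywood boundary, inflates standard errors, and lets a significance
cascade remove paths the published final models retain.

Observed behaviour on the printed matrix (`analysis/04_model_search.R`):
the area-based search removes MAT, TSN and TSP and retains the potassium
path, matching the published exclusions; the mass-based search removes
TSN but keeps a marginal direct MAT path that AIC will not surrender
(dropping it raises AIC by about half a unit) — a divergence we attribute
to input rounding and to the prior's misspecified three-indicator latent.

## Synthetic data: what it does and does not emulate

`simulate_model()` draws independent Gaussian shocks (respecting declared
residual covariances), propagates them through the path structure, and
optionally rescales columns to the published means and SDs (SD
reconstructed as mean·CV/100; rescaling is cosmetic — correlations are
scale-free — and off by default in tests). `exact_moment_sample()`
whitens-and-recolors a Gaussian draw so its sample correlation matrix
equals a target *exactly*, bridging raw-data operations and the printed
matrix: by sufficiency, any moment-based fit on such a table equals the
fit on the target.

The generator emulates the multivariate Gaussian, independent-tree world
the ML discrepancy assumes. It does not emulate: within-site dependence
from sampling three trees per elevation site, non-Gaussian trait
distributions, measurement error beyond the latent structure, or the
published summary table's internal inconsistency (the LDW row's printed
minimum equals its mean; the fixture stores it as printed and flags it).
Passing tests therefore demonstrate correctness of the estimation
machinery under its own assumptions, not robustness to their violation.

## Problem sizes and tolerances used in validation

The test suite fits population-moment self-consistency checks to 1e-10,
compares standardized estimates on 20 random recursive models against the
closed-form equation-wise ML oracle to 1e-3, verifies the exact-moment
round trip to 1e-10, and runs recovery at n = 5000 (single-model bias,
±0.03 on the replicate mean) and n = 90 (120 replicates; bias ±0.02 and
SD/SE within 25% on covariance input). The search-recovery experiment in
the analysis driver uses 20 noisy replicates at n = 90 with one spurious
extra path; backward AIC is expected to retain a spurious edge in roughly
16% of replicates (the chi-square(1) mass above 2), and the observed
recovery rate matches. These sizes are the package's validation design;
larger experiments change none of the conclusions.

## Known limitations

* The printed two-decimal correlations are not the raw data. Refitting
  them shifts chi-square by about +1.5 on the mass-based model and the
  explained variance of Nmass by about −0.02, and moves the largest
  variance-partition cells by up to ~1.7 percentage points; all
  standardized paths and effects still land within ±0.015 of the
  published values (`analysis/02`, `analysis/03`).
* Standard errors on correlation input are approximate (see above);
  significance reported for the refits should be read accordingly.
* Only recursive (acyclic) models, single-group analyses and complete
  data are supported; there is no robust/weighted estimation, no FIML,
  and no bootstrap for composite effects.
* The reconstructed prior model is a documented assumption (direct
  climate-to-nitrogen paths and a climate covariance included); the
  search's behaviour is defined relative to it.
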