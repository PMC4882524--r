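# foliarsem

Structural equation modelling of the determinants of leaf nitrogen in
*Quercus wutaishanica* across the Loess Plateau — and a general,
dependency-light toolkit for small recursive latent-variable path models
fitted by maximum likelihood from a correlation or covariance matrix.

Leaf nitrogen per unit mass (Nmass) and per unit area (Narea) respond
jointly to climate (MAT, MAP), topsoil chemistry (TSN, TSP, TSK) and leaf
morphology (SLA, LS, LDW). The package refits the study's two final
models — each with a two-indicator latent morphology factor (LMT1 =~
SLA + LS for Nmass; LMT2 =~ SLA + LDW for Narea) — from the published
10-variable correlation matrix of 90 trees, then decomposes effects and
partitions explained variance.

At its core sits the RAM formulation: implied covariance
`Σ(θ) = F (I−A)⁻¹ S (I−A)⁻ᵀ Fᵀ`, ML discrepancy
`F_ML = ln|Σ| − ln|S| + tr(SΣ⁻¹) − p`, model chi-square `(n−1)·F_min`,
`df = p(p+1)/2 − t`, standardized solutions, RMSEA/AGFI/CFI/AIC, total
effects `(I−A*)⁻¹ − I`, and an exact orthogonal-shock variance partition
whose group shares sum to `100·R²`. An AIC-guided backward search
simplifies a full prior model; Gaussian simulators (including samples
whose *sample* correlation matrix equals a target exactly) validate every
stage end to end.

## Worked example

```r
library(foliarsem)

m2  <- table2_fixture()          # printed correlation matrix, n = 90
mod <- paper_models()$narea_final
fit <- fit_ml(mod, m2)
fit
#> <sem_fit: 6 observed, 15 free parameters, converged>
#>   chisq = 7.927 on df = 6 (p = 0.244), F_ml = 0.089067
#>   RMSEA = 0.060  AGFI = 0.904  CFI = 0.988  AIC = 37.93
#>   standardized solution:
#>        label     kind estimate
#>     MAP->TSK     path   -0.530
#>     MAP->TSP     path   -0.360
#>    TSP->LMT2     path   -0.386
#>   TSP->Narea     path   -0.334
#>   TSK->Narea     path    0.508
#>  LMT2->Narea     path   -0.826
#>    load(LDW)  loading   -0.494
#>     TSK~~TSP      cov    0.389
#>     var(MAP) variance    1.000
#>     var(TSP) variance    0.870
#>     var(TSK) variance    0.719
#>   var(Narea) variance    0.170
#>     var(SLA) variance    0.439
#>     var(LDW) variance    0.756
#>    var(LMT2) variance    0.851

effect_table(fit, c("MAP", "TSK", "TSP", "LMT2"), "Narea")
#>   source target     direct   indirect       total     direct_p
#> 1    MAP  Narea  0.0000000 -0.2638895 -0.26388951           NA
#> 2    TSK  Narea  0.5084153  0.0000000  0.50841531 2.508910e-09
#> 3    TSP  Narea -0.3341624  0.3186885 -0.01547387 5.782479e-03
#> 4   LMT2  Narea -0.8258936  0.0000000 -0.82589355 7.710651e-05

partition_all(fit, list(MAP = "MAP", `TSK and TSP` = c("TSK", "TSP"),
                        LMT2 = "LMT2"))
#>   response       MAP TSK and TSP     LMT2    total
#> 1      TSP 12.959998     0.00000  0.00000 12.96000
#> 2      TSK 28.089999     0.00000  0.00000 28.09000
#> 3    Narea  6.963767    17.99620 58.05378 83.01375
#> 4     LMT2  1.929699    12.95996  0.00000 14.88966
```

Reading: soil potassium raises Narea directly (standardized 0.508); soil
phosphorus pushes Narea down directly (−0.334) but back up through the
morphology factor (+0.319), a near-perfect cancellation (total −0.015);
precipitation acts only indirectly (−0.264). The model explains 83% of
the variance in Narea, of which the morphology factor contributes 58
percentage points. The published values (0.495, −0.326, 0.321, −0.005,
−0.259, 83%, 58.9) sit within ±0.015 / ±0.9 of these refits; remaining
gaps come from the two-decimal rounding of the printed correlations.

The analysis is organised as numbered drivers over the package:

| script | stage |
|---|---|
| `analysis/01_descriptives.R` | fixtures, exact-moment synthetic individuals, summaries |
| `analysis/02_fit_final_models.R` | both refits + fit-index table vs published values |
| `analysis/03_effects_varpart.R` | effect decomposition + variance partition vs published tables |
| `analysis/04_model_search.R` | backward AIC search from the reconstructed prior |
| `analysis/05_parameter_recovery.R` | simulation validation (bias, SE calibration, search recovery) |

Each writes plain CSV/JSON under `results/`.

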