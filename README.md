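# deformBAT

Deformation-band radiomics for quantifying tumor mass effect in the
brain-around-tumor (BAT) region, with molecular-subgroup association
testing and survival risk stratification — aimed at researchers studying
pediatric medulloblastoma (and similar mass-occupying brain tumors) on
Gd-T1w MRI.

## What it computes

A growing tumor displaces the surrounding parenchyma. `deformBAT` measures
that displacement against an age-matched healthy atlas and summarizes it
around the infiltrating tumor edge:

1. **Preprocessing** — multiplicative bias-field correction;
   histogram-landmark (Nyúl-style) intensity standardization against a
   cohort template.
2. **Deformation magnitudes** — age-bracket atlas selection (0–1, 1–5,
   5–10, 10–18 y); deformable registration (mutual information, cubic
   B-spline free-form deformation, affine initialization) with the tumor
   mask excluded from the metric; field inversion; per-voxel Euclidean norm
   ‖u(x)‖ in mm.
3. **Band features** — exact Euclidean distance d from the tumor edge; 12
   cumulative annular bands (0 < d ≤ 5k mm, k = 1…12, covering 60 mm); per
   band the mean (M), median (MD), standard deviation (STD), skewness (SK)
   and excess kurtosis (K) of ‖u‖: the 60-feature descriptor `M_5 … K_60`.
4. **Subgroup statistics** — correlation pruning, z-scoring, one-way ANOVA
   per feature across WNT / SHH / Group 3 / Group 4 with Tukey HSD
   post-hoc; one-vs-all Fisher / chi-square tests for semantic features;
   Ward hierarchical clustering.
5. **Survival** — stratified 70/30 split; LASSO-Cox (3-fold CV) selection;
   the radiomic risk score RRS(x) = Σⱼ βⱼ zⱼ(x); a log-rank-maximizing
   cutpoint learned on training scores; Kaplan–Meier / log-rank; Cox models
   with per-stratum hazard ratios and Harrell's C-index; McNemar and
   chi-square agreement tests between stratifications.

Because real cohorts of this kind are not public, the package includes a
synthetic phantom generator (`phantomAtlas()`, `simulateSubject()`,
`simulateCohort()`) whose displacement fields follow the closed form
m(d, θ) = A₀ (1 + h cos kθ) e^(−d/τ) and whose survival times come from a
stated proportional-hazards model on the true band features — every stage
of the pipeline is testable against ground truth.

## Worked example

```r
library(deformBAT)

## a synthetic subject with known ground truth
pc  <- phantomConfig()                       # 64^3 voxels at 2.5 mm
atl <- phantomAtlas(pc)
dc  <- deformationConfig(amplitude_A0_mm = 4, decay_tau_mm = 10,
                         heterogeneity_h = 0.3, seed = 7)
s   <- simulateSubject(atl$volume, atl$brainMask, dc, pc)

## tumor-masked registration recovers the deformation field
fld <- registerVolumes(s$volume, atl$volume, exclusionMask = s$tumorMask)
mag <- deformationMagnitude(fld, atl$brainMask)

## the 60-feature band descriptor
f <- extractFeatures(mag, s$tumorMask, atl$brainMask)
round(f[c("M_5", "MD_10", "SK_15", "K_10")], 3)
#>    M_5  MD_10  SK_15   K_10
#>  3.647  2.765  0.708 -0.241

## compare with the analytic truth
truth <- trueBandFeatures(s$dcfg, atl$brainMask, pc$grid_shape, pc$spacing_mm)
round(truth[c("M_5", "MD_10", "SK_15", "K_10")], 3)
#>   M_5 MD_10 SK_15  K_10
#> 2.966 2.067 1.290 0.314
```

`M_5` ≈ 3–3.6 mm says the innermost 5-mm band is displaced by roughly the
injected amplitude (A₀ = 4 mm decaying over the band); positive `SK_15`
reflects the angular heterogeneity (h = 0.3) of the simulated mass effect.
The registered field tracks the truth well in magnitude (the
mean-absolute-error of ‖u‖ within 30 mm of the tumor is about 6% of A₀ on
this phantom) while the B-spline smoothness damps the higher moments —
the vignette quantifies both effects.

A cohort-level run, from simulation to risk groups:

```r
pcC <- phantomConfig(grid_shape = c(32L, 32L, 32L), spacing_mm = 5,
                     brain_semi_axes_mm = c(70, 75, 65))
coh <- simulateCohort(cohortConfig(n_subjects = 210,
                                   survival_beta = c(K_10 = 1),
                                   seed = 9001), pcC)
res <- survivalPipeline(coh$features, coh$clinical,
                        train_fraction = 0.7, folds = 3, seed = 1)
res$model@features
#> [1] "M_55" "M_60" "K_10" "K_15"
res$train$logrank$p     # 1.3e-13
res$test$logrank$p      # 0.00114
```

LASSO picks the survival-driving kurtosis feature (plus correlated
neighbours), and the transferred training cutpoint separates low- from
high-risk survival in the held-out cohort.

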