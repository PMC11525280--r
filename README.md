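# pdmotor

Quantitative motor assessment for Parkinson's disease (PD) from synchronized
multimodal recordings, and the statistical analysis layer that links those
measurements to the clinical UPDRS-III motor exam.

Clinician-rated scales such as the UPDRS-III (14 items Q18–Q31, each scored
0–4 and summed) have coarse resolution and high inter-rater variability.
`pdmotor` implements the alternative: a standardized seven-task motor battery
recorded with a 20-joint skeleton-tracking camera (30 Hz), wearable
gyroscope/accelerometer IMUs (64 Hz), and a force plate measuring the center
of pressure (CoP, 98 Hz). Each subject-visit is condensed into a canonical
vector of **62 motor metrics** — reach kinematics (mean/peak speed, duration,
smoothness = mean/peak speed ratio, path length), hand open/close timing,
3–6 Hz rest and 5–8 Hz postural tremor band-power ratios from multitaper
spectra, posturographic sway (CoP path length, component SDs, 95% covariance
ellipse, trunk jerk), and gait (stride timing from ankle gyroscope peaks,
normalized jerk). On top of the metric table the package provides:

* **PCA dimensionality curves** for UPDRS items, motor metrics, and their
  union (variance explained vs. components retained);
* **elastic-net prediction** of total UPDRS-III, minimizing
  `(1/2n)·||y − β₀ − Xβ||² + λ(α||β||₁ + (1−α)/2·||β||₂²)`
  with a grid search over (α, λ) that discards every model whose degrees of
  freedom (nonzero coefficients) exceed 50% of the cohort size, scored by
  leave-one-out cross-validation (LOOCV), plus day-2 transfer of frozen
  models and cluster-augmented variants;
* **patient phenotyping** via a self-organizing map (SOM) with Ward
  clustering of neuron weights, t-SNE + K-means, random-forest out-of-bag
  feature importance, a median-dominance table (ANOVA screen, Bonferroni
  post-hocs, highest-median wins), and the classic tremor-dominant /
  akinetic-rigid / mixed subtype ratio from UPDRS items;
* a **session simulator** generating the full 14-recording protocol with
  severity-dependent kinematics and ordinally linked synthetic UPDRS exams,
  used for validation and parameter-recovery studies.

For whom: movement-disorder researchers and biostatisticians working with
wearable/camera digital biomarkers who need a reproducible, testable
reference implementation of this pipeline; the simulator makes every method
exercisable without access to clinical recordings.

## Worked example

Simulate a 10-subject cohort, extract the metric battery, and predict the
UPDRS-III total:

```r
library(pdmotor)

cohort  <- simulate_cohort(sim_config(n_subjects = 10, seed = 7))
metrics <- extract_cohort(cohort$sessions)
dim(metrics[metric_inventory()$metric])
#> [1] 10 62

dplyr::select(metrics, subject_id, t1a_mean_speed_mean, t5a_power_ratio_mt,
              t6_eo_cop_path_length)[1:3, ]
#> # A tibble: 3 x 4
#>   subject_id t1a_mean_speed_mean t5a_power_ratio_mt t6_eo_cop_path_length
#>   <chr>                    <dbl>              <dbl>                 <dbl>
#> 1 S001                     0.321              0.999                  84.5
#> 2 S002                     0.514              0.953                  29.8
#> 3 S003                     0.447              0.998                  23.7

gs <- enet_grid_search(impute_median(metrics[metric_inventory()$metric]),
                       cohort$updrs$total)
glance(gs$cv)
#> # A tibble: 1 x 4
#>     mae    r2 scheme     n
#>   <dbl> <dbl> <chr>  <int>
#> 1  4.78 0.818 loo       10
```

`t1a_mean_speed_mean` is the average per-movement wrist speed (m/s) during
continuous elbow flexion/extension — lower with more bradykinesia;
`t5a_power_ratio_mt` is the fraction of rest-hold acceleration power in the
3–6 Hz tremor band; `t6_eo_cop_path_length` is the eyes-open sway path in
cm. The fitted model's LOOCV mean absolute error is in UPDRS-III points
(here 4.8 points with R² = 0.82 on a 10-subject synthetic cohort; the model
df never exceeds 50% of the cohort size by construction).

Phenotype the cohort (on realistic sizes, n ≥ 50):

```r
z   <- standardize_table(impute_median(metrics[metric_inventory()$metric]))
som <- train_som(z, grid = c(6, 6), epochs = 200, restarts = 10, seed = 7)
ward_cut(som, k = 3)$assignments
```

A complete run — simulate, extract, PCA, predict, cluster, report — is one
call:

```r
run_pipeline(list(seed = 7, simulator = list(n_subjects = 50)),
             out_dir = "pdmotor_out")
```

or, from a shell, via the thin CLI wrapper:

```sh
Rscript inst/cli/pdmotor.R all --seed 7 --n 50 --out pdmotor_out
```

## Package layout

* `R/session-io.R` — on-disk session format (manifest + CSV streams),
  validation, task windows, cropping
* `R/signal-prep.R` — zero-phase FIR/Butterworth filters, derivatives,
  DPSS multitaper spectra, band-power ratios, jerk
* `R/segmentation.R` — movement segmentation, hand-open and stride events
* `R/motor-metrics.R` — the 62-metric battery
* `R/dimensionality.R`, `R/prediction.R`, `R/phenotyping.R` — the analysis
  layer
* `R/simulator.R` — the synthetic-session generator
* `R/pipeline.R`, `inst/cli/pdmotor.R` — orchestration
* `vignettes/pdmotor-methods.Rmd` — the full methods account: model
  assumptions, parameter choices, simulator scope, limitations
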