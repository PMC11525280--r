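---
title: "Methods: multimodal motor metrics and their analysis layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal motor metrics and their analysis layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdmotor)
```

## The measurement model

`pdmotor` quantifies Parkinson's disease motor impairment from a
standardized battery of seven tasks recorded with three synchronized sensor
modalities: a depth camera tracking a 20-joint skeleton at a nominal 30 Hz,
three-axis gyroscope/accelerometer IMUs at 64 Hz (index finger for the
seated tasks, L5 near the body's center of mass for balance and gait, ankles
for gait), and a force plate sampling the center of pressure (CoP) at 98 Hz.
An experimenter-driven marker channel brackets each task; the active window
of a task always runs from the first to the last marker event.

All streams of a session share one clock; synchronization is assumed done
upstream of this package, and a skew of one nominal sample is tolerated at
crop boundaries. Camera coordinates are meters with x lateral (+ right),
y vertical (+ up), z depth (+ away from the camera); the paperless parts of
this convention (the axis directions, and the IMU axis-to-anatomy mapping
with `accel_x` medio-lateral and `accel_z` antero-posterior on the trunk)
are package conventions used consistently by the simulator and the metric
layer — they are definitions, not estimates.

The battery condenses each subject-visit into exactly **62 named metrics**
(`metric_inventory()`). The inventory is a documented reconstruction
constrained to that total: the three reaching tasks contribute 10 metrics
each (mean and SD of per-movement mean speed, peak speed, duration and
smoothness, plus movement count and wrist path length), the two hand
open/close tasks 3 each (movement time and inter-peak-interval mean/SD), the
complex sequence its total time, the two tremor holds 2 each (multitaper and
periodogram band-power ratios), the two balance conditions 8 each (CoP path
length, component SDs, 95% ellipse axes and area, trunk jerk mean and peak),
and gait 5 (total walk time, normalized jerk, stride duration mean/SD,
stride count). Task time is computed for every task but enters the inventory
only through the complex-sequence total time, the open/close movement time,
and the gait walk time; elsewhere it is an intermediate. Missing inputs
produce flagged `NA` metrics, never a shorter vector.

## Signal processing choices

* **Filters.** Camera trajectories are smoothed with a 31-tap Hamming-window
  linear-phase FIR low-pass at 10 Hz; IMU channels use a 4th-order
  Butterworth low-pass at 5 Hz. Both are applied forward-backward on an
  odd-reflection padded copy of the signal, so outputs have zero phase lag
  (no timing bias in segmentation) and the designed magnitude response is
  squared. "4th order" refers to the designed order.
* **Derivatives** are central differences with one-sided ends — simple,
  linear, and directly checkable against analytic derivatives. The first
  and last 0.25 s of any filtered-then-differentiated signal are excluded
  from peak statistics to suppress edge transients.
* **Spectra.** Tremor power ratios integrate band power over total power on
  the demeaned acceleration amplitude (Euclidean norm of the three
  accelerometer axes, mean removed so the gravity component drops out).
  The primary estimate uses DPSS multitapers with time-bandwidth NW = 4 and
  7 tapers; a single Hann-taper periodogram is the secondary estimate. Total
  power is integrated from 0.5 Hz to Nyquist: excluding the lowest bins
  keeps DC and slow gravity leakage out of the denominator, without which
  the ratio would depend on hold posture rather than tremor. The rest band
  is 3–6 Hz, the postural band 5–8 Hz. DPSS tapers are computed from the
  standard symmetric tridiagonal eigenproblem and cached per signal length.
  The alternative tremor quantifications — mean in-band power and mean
  total power under either estimator — are computed by
  `tremor_aux_metrics()` as auxiliary outputs outside the 62-metric
  inventory.
* **Sway ellipse.** The "ellipse fitting CoP oscillations" is made precise
  as the 95% covariance ellipse: axis lengths are
  `2 * sqrt(qchisq(.95, 2) * eigenvalue)` of the 2×2 CoP covariance and the
  area is `pi * qchisq(.95, 2) * sqrt(det)`.

## Movement segmentation

Elementary movements are humps of the wrist speed profile. Local maxima
(spaced at least 0.25 s, above a 10% amplitude floor) are candidate
movements; the minimum between two adjacent maxima splits them when it
drops below θ = 0.2 times the smaller peak, otherwise the maxima merge into
one movement. Segments run **minimum-to-minimum**, with the outer segments
extending to the window edges. This makes the closed forms exact: a single
minimum-jerk reach of amplitude *d* and duration *T* spans its whole
duration, with peak speed 1.875·d/T, mean speed d/T, and smoothness
(mean/peak) 1/1.875 ≈ 0.533.

Severely bradykinetic profiles can fail to drop below threshold between
movements. When fewer movements than the protocol's expected count are
found and a gyroscope stream is available, boundaries are refined from zero
crossings of the 5 Hz low-passed `gyro_x` — the planned repetition count
only *triggers* this fallback; it never forces a count.

Discrete events use prominence-based peak picking with an earliest-wins tie
break. Hand-openings are positive `gyro_x` peaks with prominence at least
half the median candidate prominence (candidates above a 10% amplitude
floor, which keeps sensor-noise maxima from dominating the median) and
0.25 s spacing. Strides are `gyro_z` peaks above the signal mean plus one
SD — with an absolute floor of 0.5 rad/s, far below swing-phase shank
rotation, so a stride-free noise trace yields zero peaks — and a 0.5 s
refractory period. All thresholds are exposed as arguments.

## Dimensionality and prediction

Feature tables are standardized per variable (mean removed, SD with the
n − 1 denominator; constant columns dropped with a warning), and missing
metrics are imputed by the cohort median before any multivariate analysis.
PCA is the eigendecomposition of this standardized table, reported as
variance-explained curves for UPDRS-III items, motor metrics, and their
column-concatenated union.

Total UPDRS-III is predicted by an elastic net minimizing

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 +
  \lambda\left(\alpha\lVert\beta\rVert_1 +
  \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

solved by coordinate descent. A sweep converges when its largest
coefficient change falls below 1e-7 relative to the coefficient scale; a
plateau check on the (monotone non-increasing) objective and a 2000-sweep
cap terminate the degenerate regime — with more features than subjects and
α near 1 at small λ the minimizer is non-unique, and coefficients can
wander along flat directions indefinitely under a pure coefficient-change
rule. The test suite asserts the objective's monotone descent and checks
the solver against closed-form least squares and an independent
implementation. Model size df is the number of nonzero coefficients.
Hyperparameters come from a grid search over α ∈ {0.1, …, 1.0} and, per α,
50 log-spaced λ values from λ_max down to 10⁻³·λ_max; every (α, λ) pair
whose full-data df exceeds 50% of the cohort size is discarded — its
cross-validated score is never needed, so none is computed — and among the
survivors the pair with the highest leave-one-out R² wins (ties: smaller
df, then larger λ). Every LOOCV fold is a genuine refit with within-fold
re-standardization — no shortcut formulas — so leakage through the scaling
is impossible.

Two caveats are deliberate and documented rather than hidden. First, the
same LOOCV that selects the hyperparameters is also the reported
performance estimate (one grid search plus LOOCV, not nested
cross-validation), which is optimistically biased; the day-2 transfer
evaluation, which freezes day-1 coefficients and standardization, is the
unbiased complement. Second, df is enforced on the full-data fit;
fold-wise dfs may differ slightly.

Cluster indicators can be appended as one-hot columns penalized like any
other feature. In LOOCV the held-out subject's indicator must not use its
own label: it is assigned by retraining a SOM on the fold's training
subjects (nodes vote with the supplied labels; the held-out subject
inherits its best-matching unit's majority label) or, without a SOM
configuration, by the nearest training-cluster centroid.

## Phenotyping

Two clustering routes are compared. The visualization route embeds the
standardized metrics with t-SNE (perplexity 30, learning rate 200, up to
1000 iterations) and clusters the 2-D embedding with K-means (10 restarts).
Exact t-SNE requires perplexity ≤ (n − 1)/3, so small cohorts clamp the
perplexity with a warning — with n = 50 the effective perplexity is 16.

The primary route trains a self-organizing map (rectangular grid, Gaussian
neighborhood, learning rate decaying linearly 0.5 → 0.01 and radius
decaying linearly to 1) over every requested combination of grid size,
epochs, and initial radius, with 10 seeded restarts each, and keeps the
model with the lowest quantization error (mean distance of samples to their
best-matching unit). Ward linkage (Euclidean, `ward.D2`) on the neuron
weights is cut at k = 2, 3, 4; subjects inherit their BMU's cluster, and
cuts of one tree are nested across k.

Clusters are characterized two ways. A random-forest classifier (500 trees,
10 seeds) ranks features by mean out-of-bag permutation importance, keeping
the top ten. The dominance table screens each feature with a one-way ANOVA
across clusters (p < 0.05), runs pairwise two-sample t-tests
Bonferroni-corrected by the number of cluster pairs, and in each significant
pair credits one "win" to the cluster with the higher median; the Bonferroni
denominator and the t-test as the post-hoc family are package choices among
the reasonable options. Clinical subtypes for comparison use the classic
ratio of mean tremor item scores (Q20, Q21) to mean akinetic-rigid item
scores (Q22–Q26, Q31): tremor-dominant at ≥ 1.5, akinetic-rigid at ≤ 1/1.5,
mixed between; a zero denominator is tremor-dominant when the numerator is
positive and mixed when both are zero. Item sets and thresholds are
arguments, since ratio variants exist in the clinical literature.

## The simulator: what it emulates, and what it does not

Because no public recording set exists for this protocol, the package ships
a generator whose defaults *are* the study conditions. Five latent
severities in [0, 1] — bradykinesia, rest tremor, postural tremor, postural
instability, gait impairment — drive every stream:

* reaches are minimum-jerk strokes with duration 0.4·(1 + 1.5·s_brady) s
  (amplitude 0.35 m for elbow flexion/extension, 0.45 m hand-to-nose, ten
  repetitions with short holds between; 2 s holds in the discrete variant);
* hand open/close is a train of positive `gyro_x` bursts with period
  0.5·(1 + s_brady) s;
* tremor holds superimpose a sinusoid at a frequency drawn in-band
  (3.5–5.5 Hz rest, 5.5–7.5 Hz postural) with acceleration amplitude
  2·severity m/s², on a gravity-dominated accelerometer with 1/f plus white
  sensor noise;
* CoP sway is a mean-reverting (Ornstein–Uhlenbeck) planar walk with
  diffusion 0.09·(1 + 4·s_postural) cm/√s and an eyes-closed multiplier of
  1.5;
* gait is a train of Gaussian-windowed `gyro_z` bursts with stride period
  1.0·(1 + 0.4·s_gait) s and walk time 10 m / (1.4·(1 − 0.5·s_gait) m/s).

The proportionality constants were fixed once so that extracted metrics
fall in clinically plausible ranges (reach speeds roughly 0.5–1.6 m/s,
eyes-open sway paths roughly 20–80 cm, trunk jerk means of order
0.05–0.2 m/s³, stride times 1.0–1.4 s) and are exposed in `sim_config()`.
UPDRS-III items are generated from the same severities through a fixed
weight matrix whose rows sum to one (Q20/Q21 ← tremor, Q23–Q26/Q31 ←
bradykinesia, Q27–Q30 ← posture/gait, Q22 mixed, Q18/Q19 a broad mix), as
`clip(round(4·wᵀs + ε), 0, 4)` with per-item rater noise ε; the default
SD of 0.8 points per item corresponds to roughly 3 points of noise on the
14-item total, in the range of published inter-rater variability. Cohorts
draw domain severities around a global severity g ~ Beta(2, 2), or, in
planted-phenotype mode, around tremor-heavy / bradykinesia-heavy /
instability-heavy archetypes separated by a configurable gap (default 0.6).
An optional second visit drifts severities by SD 0.05.

What the simulator does **not** emulate matters for interpreting green
tests: there is no biomechanical coupling between joints, no medication
state dynamics, no tremor waxing-and-waning or re-emergent tremor, no
marker-timing error, no camera occlusion or swapped-joint artifacts beyond
optional flagged drop-outs, and the severity→UPDRS link is far cleaner than
clinician rating behavior. Passing parameter-recovery tests therefore shows
the pipeline is *internally consistent* — it recovers what the generator
planted, with the designed signs and orderings — not that it attains any
particular accuracy on clinical recordings.

## Numerical conventions and degenerate inputs

Coordinate descent tolerance 1e-7 on coefficient changes; session
round-trip tolerance 1e-9; equal-height adjacent peaks resolve to the
earliest sample; stride counts averaged across walks round half-up to stay
integers; camera drop-outs of at most three frames are linearly
interpolated while longer gaps flag the enclosing movement and drop it from
per-movement statistics; zero-variance features are skipped by the
dominance screen and dropped (with a warning) by standardization; an
all-constant table is an error. Simulation, SOM training, t-SNE, and forests
all take explicit seeds, and identical seeds reproduce results bitwise.

The test suite runs everything at desk scale, as a deliberate choice of
problem size: cohorts of 50 subjects for the recovery suites (ten seeds for
the prediction and phenotype-recovery properties), 12-subject two-visit
cohorts for the transfer property, and closed-form fixtures elsewhere.

## Known limitations

The 62-metric inventory is a reconstruction; other splits of the same
measurement families could total 62. The hand-open prominence floor, the
segmentation thresholds, and the subtype ratio thresholds are conventions
exposed as arguments rather than estimated quantities. LOOCV-selected
hyperparameters reported with the same LOOCV are optimistic, as noted. The
SOM is an online implementation with linear decays; batch SOMs or other
decay schedules would give slightly different codebooks (the quantization
error selection across restarts absorbs most of this variability).
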