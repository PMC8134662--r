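---
title: "Nested stroke-outcome models from lesion maps and clinical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested stroke-outcome models from lesion maps and clinical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokenest)
```

## The problem

Thirty-day NIH Stroke Scale (NIHSS) scores summarise how much neurological
deficit an ischaemic stroke patient retains a month after the event. Clinical
covariates alone (age, baseline severity, risk factors) predict this outcome
only moderately well; the infarct's location carries additional information,
because deficits arise when *eloquent* brain regions — regions whose damage
produces measurable impairment — are destroyed. `strokenest` implements and
compares two routes for injecting that imaging information into an outcome
model:

1. **Voxel-wise lesion-symptom mapping (LSM)**: at every sufficiently often
   lesioned voxel, compare the 48-hour NIHSS of patients lesioned there
   against patients spared there with the Brunner-Munzel rank test; control
   the voxel-wise false discovery rate (FDR); keep the atlas regions touched
   by surviving voxels.
2. **RReliefF**: a regression-variant Relief feature selector applied to
   region-level lesion features, weighting each feature by how much its
   differences co-occur with outcome differences among nearest neighbours.

Either route yields a region set whose lesion-overlap and tract-integrity
features feed a nested two-stage epsilon-SVR:

\[
\mathrm{NIHSS}_{30d} \sim \big(X_{\mathrm{clinical}} +
    (\mathrm{NIHSS}_{48h} \sim X_{\mathrm{imaging}})\big)
\]

The inner model predicts the 48-hour score from imaging alone; its prediction
joins the clinical features in the outer model. Region selection always
targets the 48-hour score, never the 30-day outcome, so selected
structure-function relationships reflect the primary deficit rather than
late, indirect processes — and so no information about the prediction target
leaks into feature selection.

Because suitable patient-level trial data are not publicly available, the
package ships a synthetic cohort generator with a fully known generative
model. Every verification study in the test suite runs against cohorts whose
ground truth is known by construction.

## The synthetic generator

`make_toy_atlas()` partitions a 32×32×32 lattice exhaustively: axis-aligned
white-matter (WM) tract bundles are placed first, and the remaining volume
is split into grey-matter (GM) parcels as the Voronoi cells of random seed
points (default 20 GM + 4 WM). Two properties of real parcellations are
preserved on purpose. First, coverage is exhaustive — every lesion overlaps
*some* region. If large parts of the volume were unlabelled, many patients
would share identical all-zero feature rows, and those clusters contribute
outcome-difference mass with zero feature differences to Relief-style
weights, biasing every weight negative. Second, the region count is
generous: Relief's neighbour distance is summed over feature columns, and
with very few columns a single strongly informative column dominates the
metric, suppressing its own observed differences among neighbours. Real
fused GM/WM parcellations have hundreds of regions; two dozen on a full
partition is the smallest scale at which the toy problem behaves
qualitatively like the real one.

`simulate_cohort()` draws, per patient:

* **A lesion**: an axis-aligned ellipsoid with jittered radii, trimmed to an
  exact target volume (default 100–2000 voxels, a realistic territorial-
  infarct fraction of this brain-sized grid), whose centre falls inside a
  configurable "arterial territory" ball with probability 0.8 and uniformly
  otherwise. `eloquent_defaults()` centres that territory on a compact
  cluster of GM regions — mirroring the clinical fact that infarcts
  concentrate in the middle-cerebral-artery territory, which is also where
  the deficit-relevant regions sit.
* **Clinical covariates** anchored to published trial characteristics:
  age ~ N(69, 14) truncated to [30, 95], glucose, hematocrit, blood
  pressure, onset-to-admission time, and Bernoulli risk factors (atrial
  fibrillation, hypertension, hyperlipidemia, diabetes, smoking, treatment).
  Diabetes and smoking carry no outcome effect by default, so a correct
  feature selector should drop them.
* **Outcomes**, as a causal chain with all coefficients in the config:
  - eloquent lesion load \(L = \sum_r \beta_r\,\mathrm{overlap}_r +
    \sum_t \gamma_t (1-\mathrm{integrity}_t)\);
  - baseline NIHSS \(= \mathrm{clip}_{2..30}(\mathrm{round}(12 + 0.5 L +
    \varepsilon_b))\), \(\varepsilon_b \sim N(0, 5.5)\);
  - 48-hour NIHSS \(= \mathrm{clip}_{0..42}(\mathrm{round}(0.9\,b + L +
    \varepsilon_1))\), \(\varepsilon_1 \sim N(0, 3)\);
  - 30-day NIHSS \(= \mathrm{clip}_{0..42}(\mathrm{round}(-1.5 +
    0.85\,\mathrm{NIHSS}_{48h} + \delta^T x_c + \varepsilon_2))\),
    \(\varepsilon_2 \sim N(0, 3)\).

Coupling baseline severity to the same lesion load is a deliberate design
choice. Presenting NIHSS is caused by the infarct that is later segmented,
and lesion volume correlates strongly with admission severity in real
cohorts. An independently drawn baseline would act as irreducible noise on
the 48-hour score; with the coupling, imaging-derived features explain about
half of the 48-hour variance under the default effect sizes (β = 8 NIHSS
points per unit overlap for three eloquent GM regions, γ = 6 per unit
tract-integrity loss), while the marginal baseline distribution keeps the
published anchors (median ≈ 14–15, SD ≈ 6). Under these defaults a
simulated cohort has median 48-hour NIHSS ≈ 16–17 with well under 1% of
scores at the scale ceiling of 42.

Determinism: each patient draws from a sub-stream derived from the master
seed, so cohorts with the same seed are identical patient-by-patient even
when their sizes differ, and all on-disk output (NIfTI masks, CSV, JSON) is
byte-identical across re-runs.

What the generator does **not** emulate: anatomically shaped infarcts,
registration error, partial-volume effects, soft (probabilistic) atlases,
bilateral or haemorrhagic lesions, and any correlation between risk factors
and lesion location. Passing tests therefore demonstrate correctness of the
statistical machinery under a known model, not clinical performance.

## Feature definitions

* `overlap_fraction()`: \(|lesion \cap region| / |region|\).
* `tract_integrity()`: slice the tract along its declared axis; per slice
  compute the spared fraction \(1 - |lesion \cap tract \cap slice| /
  |tract \cap slice|\); summarise with the **minimum** by default. The
  minimum was chosen because a single fully transected cross-section
  disconnects a tract regardless of how intact the rest is; a `mean` option
  exists for sensitivity analyses. The cross-section is measured as a voxel
  count rather than a geometric width, which is the robust choice on coarse
  lattices.
* `coverage_filter()`: a voxel (or region) enters the analysis only if at
  least 10% of patients have a lesion there — inclusive, so 2 of 20
  patients is retained. Region-level "affected" means any lesioned voxel
  inside the region.

## The LSM arm

`bm_test()` implements the Brunner-Munzel statistic from pooled mid-ranks
with separate rank-variance estimates per group and a Satterthwaite-type
t-approximation, two-sided. The test is preferred over the rank-sum test in
lesion mapping because voxel-wise group sizes are very unbalanced and NIHSS
distributions are tied and skewed; Brunner-Munzel tolerates ties and
unequal variances.

Numerical decisions:

* Voxels need at least 2 patients on each side (the variance estimators
  divide by \(n_i - 1\)) in addition to the coverage filter.
* Voxels with zero rank variance on both sides (e.g. complete separation)
  are flagged *degenerate* and excluded from the FDR pool rather than
  assigned an extreme p-value — the conservative choice, made explicit in
  the returned map.
* FDR control is Benjamini-Hochberg step-up (`fdr_adjust()`), the standard
  choice in voxel-wise mapping; the adjusted values satisfy
  \(q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j\).
* Surviving voxels (q ≤ 0.05 by default) receive weight \(|W|\); only the
  zero/non-zero distinction drives region selection, the magnitude is kept
  for reporting. Voxels sharing an identical lesioned-patient set share one
  test result, which the implementation exploits.

## The RReliefF arm

`rrelieff()` accumulates, over sampled instances and their k nearest
neighbours (Manhattan distance on min-max-normalised features), the
probability-style quantities \(N_{dC}\), \(N_{dA}\), \(N_{dC \wedge dA}\)
and returns \(W[A] = N_{dC\wedge dA}/N_{dC} - (N_{dA}-N_{dC\wedge
dA})/(m-N_{dC})\), in [-1, 1].

Decisions worth knowing:

* Neighbour influence is uniform 1/k (the canonical exponential rank-decay
  is a generalisation; uniform matches common package defaults and keeps
  the brute-force oracle trivial).
* Distance ties are broken by lowest instance index. Distances are
  quantised to 10 decimals before ordering because mathematically equal
  sums can differ at 1e-16 depending on floating-point summation order.
* A zero-range feature is defined to have difference 0 everywhere, hence
  weight exactly 0.
* The pipeline default is the literature setting m = 10 sampled instances
  with k = 5 neighbours. m = 10 is high-variance; `exhaustive = TRUE`
  replaces sampling with one deterministic pass over all instances and is
  what the package's own simulation studies use, for reproducibility.
* Feature selection keeps strictly positive weights by default (the
  data-determined region count this produces matches how the method is
  used in practice); top-j and threshold rules are available. A region is
  retained if any of its feature columns is selected, and all its feature
  kinds then enter the model.
* Applied twice: to imaging features against the 48-hour score (region
  selection) and to clinical candidates against the 30-day score
  (clinical-feature selection for all arms).

## The nested model

`fit_svr()` wraps an epsilon-SVR with radial kernel; inputs are
standardised with training-set statistics only, zero-variance columns are
dropped with a warning, and the default hyperparameters are C = 1,
epsilon = 0.1, gamma = 1/d on standardised inputs (none of these are
prescribed by the method; they are the library defaults and behave well on
NIHSS scales).

`fit_nested()` fits the inner imaging model on training rows, then fits the
outer model on clinical features plus the inner prediction. The inner
predictions used for *outer training* are out-of-fold (deterministic
5-fold assignment by rank of the inner target) so the outer model sees
realistic inner-model errors instead of optimistic resubstitution fits;
`inner_oof = FALSE` gives the plain stacked variant. Predictions are
clamped to the valid NIHSS range [0, 42] and not rounded.

`stratified_split()` bins the 30-day outcome into quartiles and samples
80/20 within bins (largest-remainder rounding hits the global count
exactly; undersized bins merge downward with a warning), so severity is
represented in both subsets and all arms share one split, making the MAE
comparisons paired.

## Evaluation

`run_experiment()` executes split → selection (training rows only) → fits →
test metrics for the three arms M_CLINICAL, M_RELIEF, M_LSM and reports
MAE, RMSE, R² (defined as \(1 - SS_{res}/SS_{tot}\) on the test set — it
can be negative, and it is not a squared correlation), a per-model p-value,
and pairwise MAE comparisons.

Two interpretations are deliberate and documented rather than prescribed:
the per-model p-value is the two-sided test of zero Pearson association
between predictions and observations, and the between-model comparison is a
two-sided paired Wilcoxon signed-rank test on per-patient absolute errors
(chosen over a paired t-test because NIHSS errors are discrete, tied and
non-normal on small test sets).

## Verification studies and their scales

The test suite re-derives every statistic against independent brute-force
oracles (explicit mid-rank counting for Brunner-Munzel, literal step-up
minimisation for FDR, straight-loop accumulation for RReliefF) and runs
four simulation studies under the default study conditions:

* **Null calibration**: 100 permutations of the 48-hour score on an
  n = 200 cohort; the mean fraction of tested voxels with q ≤ 0.05 stays
  within two Monte-Carlo standard errors of 0.05 (in practice it is nearly
  zero, as expected under strong FDR control).
* **Eloquent-region recovery**: 20 cohorts of n = 200 with three β = 8 GM
  regions and noise SD 3; LSM recovers all three in ≥ 90% of seeds.
* **Feature-selection sanity**: informative features outrank 20 pure-noise
  features in ≥ 95 of 100 runs at n = 200.
* **Model ordering**: 20 cohorts of n = 400; both nested arms beat the
  clinical-only arm on test MAE and R² in ≥ 90% of seeds while the two
  nested arms show no significant paired MAE difference (α = 0.05) in
  ≥ 80% — the qualitative ordering the nested design is meant to produce.

These problem sizes keep the full suite in the minutes range while leaving
the Monte-Carlo margins comfortable.

## Known limitations

* The toy atlas is geometric, not anatomical; hemispheric asymmetry and
  cortical topology are absent.
* Effects are linear in overlap/integrity by construction, which favours
  all three models equally but cannot probe non-linear structure-function
  relationships.
* The paper-style sampled RReliefF (m = 10) is noisy by design; region
  selections vary across seeds. Exhaustive mode removes the sampling noise
  but not the neighbourhood noise.
* `compare_mae` treats patients as exchangeable pairs; clustering by site
  or operator, present in real pooled trials, is not modelled.
* A single 80/20 split (matching the comparative design this package
  implements) yields one region set per arm and interpretable comparisons,
  at the cost of split-to-split variance that repeated cross-validation
  would average away.
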