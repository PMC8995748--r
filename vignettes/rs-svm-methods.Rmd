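---
title: "Random-survey SVM feature selection for voxel-based morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-survey SVM feature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Voxel-based morphometry (VBM) summarizes a structural MRI scan as a 3D
map of gray-matter density (GMD), one value per voxel. In
neurodegenerative disease — Alzheimer's disease being the motivating
case — gray matter is lost in spatially contiguous regions, so a
disease-versus-control contrast lives in a small subset of the
hundreds of thousands of voxels in a whole-brain map. The statistical
difficulty is the usual one: a few hundred subjects against tens of
thousands of candidate voxel features. `rssvm` implements a
feature-detection and classification pipeline built around a
*random-survey* support vector machine: instead of ranking single
voxels, it repeatedly draws small random subsets ("surveys") of voxel
columns, scores each subset with a tuned kernel SVM, and keeps the
subset that classifies a held-out validation set best.

## Pipeline

1. **Group summaries.** Each group's maps are collapsed voxel-wise to
   a weighted mean vector — M for disease, N for control. The weights
   are exposed (`compute_group_matrices(weights=)`) but default to
   uniform: the source description of the "weighted process" never
   defines its weights, and the uniform mean is the simplest reading
   consistent with what follows.
2. **Equal-voxel deletion.** Voxel i survives iff |M[i] − N[i]| >
   `tol`. Equal voxels carry no between-group signal. Exact float
   equality is fragile, so `tol` defaults to 1e-12 (absolute). The
   retained voxels keep their original linear index and (x, y, z)
   coordinate; the flatten convention is column-major, 0-based
   (x fastest), and is written into every output file.
3. **Similarity bounds.** For retained voxels i, j the similarity is
   the squared distance in the (disease, control) plane:
   ρ = (vm_i − vm_j)² + (vn_i − vn_j)², computed blockwise (g
   contiguous, near-equal blocks give g(g+1)/2 matrices; 55 for
   g = 10). The survey-size interval [C_max, C_min] counts the voxel
   rows participating in entries tied with the global minimum
   (C_min) and maximum (C_max) of ρ, self-pairs excluded.
4. **Random surveys.** Each survey draws l ~ Uniform{C_max, …,
   C_min} distinct columns; a soft-margin SVM (linear and RBF
   kernels) is tuned by grid search on a stratified 6:2:2
   train/validation/test split and the survey with the best
   validation accuracy wins (ties: smaller survey, then earlier
   survey). The winner's test-set metrics are the headline numbers.
5. **Comparison.** Linear regression, Lasso, PLS and a plain SVM are
   run under one fit/tune/predict contract, by default on the same
   selected columns, across repeated splits.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tol` | 1e-12 | absolute equal-voxel deletion tolerance (density units) |
| `g` | 10 | similarity block count; bounds are invariant to it |
| `extremum_tol` | 1e-9 | relative tie tolerance at the ρ extrema |
| `C`, `gamma` grid | {0.1,1,10,100} × {0.001,…,1} | SVM search grid; the conventional start point C = 1, gamma = 0.5 is always a member |
| `n_surveys` | 200 | survey draws per run |
| `ratios` | 6:2:2 | split; other ratios require an explicit override |
| `lambda` grid | 0.001–1 | Lasso penalty (per-sample objective scale) |
| `n_components` grid | 1–5 | PLS latent components |

The number of surveys is not stated by the method's source; 200 gives
a high probability that at least one survey contains informative
voxels at realistic informative-fractions (e.g. 40 of 1,200 voxels
and l = 2 give a ~6.5% hit rate per survey, so ≥ 1 hit in 200 surveys
with probability 1 − 10⁻⁶) while keeping a desk-scale run under ten
seconds.

## The synthetic cohort: what it emulates and what it does not

There is no redistributable imaging cohort, so every stage is
exercised on generated data. A cohort shares one smooth baseline
field (uniform noise smoothed by a separable Gaussian, sd 2 voxels,
rescaled to [0.3, 0.7] — mimicking the smoothness of FWHM-filtered
GMD maps without implementing an SPM pipeline); the disease group
loses `effect_size` density (default 0.3) at a contiguous blob of
informative voxels grown by random nearest-neighbour accretion
(atrophy is contiguous; a `scattered` layout exists for contrast);
i.i.d. Gaussian noise (default sd 0.05) is added per subject; values
are clipped to [0, 1]. The planted mask is returned, so selection can
be scored for recovery.

What the generator does *not* model: registration error, partial
volume effects, covariates (age, sex, education), spatially
correlated noise, or any claim about the intensity distribution of
real ADNI maps. A green test on this generator therefore establishes
that the pipeline's machinery is correct and that it recovers planted
contiguous signal under clean conditions — not that it attains any
particular accuracy on real MRI data.

## Numerical choices

- **SVM solver.** The dual is solved by a sequential minimal
  optimization (SMO) loop in C++ with maximal-violating-pair
  selection, KKT-gap tolerance 1e-8. Tests verify the objective
  against an independent quadratic-programming solve: the primal QP
  for the linear kernel (its Hessian is the identity on w, so it is
  well conditioned even when the rank-deficient linear-kernel dual is
  not) and the ridged dual QP for the RBF kernel.
- **Lasso.** Cyclic coordinate descent with the closed-form
  soft-threshold update on centered data; stopping requires both the
  objective decrease and the largest coefficient move to settle
  (tolerance 1e-8, at most 10,000 sweeps). Verified against the
  orthonormal-design closed form and against glmnet (with the
  penalty rescaled to glmnet's ½-RSS convention).
- **PLS.** NIPALS with deflation; with a univariate response the
  inner iteration converges in one step. Scores are orthogonal by
  construction; with a full component set on full-rank tall data the
  predictions coincide with least squares.
- **Linear regression.** SVD pseudoinverse on centered data, so
  underdetermined fits return the minimum-norm solution.
- **Ties and degeneracy.** Grid-search ties break toward smaller C,
  then smaller gamma, then linear before RBF; survey ties toward the
  smaller survey, then the earlier one. Metrics with zero
  denominators are flagged `undefined` (NA), never silently zero.
  ROC ties are grouped, making the trapezoidal AUC equal the
  Mann-Whitney statistic with ½-credit for ties.
- **F-measure.** The weighted form F = (α²+1)PR / (α²(P+R)) is kept
  exactly as its source prints it, although it differs from the
  conventional F_β denominator for α ≠ 1; at the default α = 1 both
  reduce to 2PR/(P+R). Likewise, the printed confusion identity
  "FP + FN = N" is treated as a typo for FP + TN = N, since the four
  cases must partition the sample.
- **Positive class.** +1 (healthy control); disease is −1. This
  orientation is recorded in output headers.

## Design decisions taken where the method's description is open

- **M and N as per-voxel summaries.** Whether the group matrices are
  subject-by-voxel or per-voxel summaries is ambiguous; the per-voxel
  summary reading is adopted because the similarity statistic treats
  (vm_i, vn_i) as a single 2-vector per voxel.
- **Extremum counting.** "The number of minimal/maximal ρ" has no
  stated formula. It is read as the count of voxel rows touching a
  tied global extremum, with a relative tie tolerance. This makes
  C_min (ties among near-duplicate voxels at ρ ≈ 0) naturally the
  larger count, matching the published ordering C_min > C_max. If a
  dataset nevertheless inverts them, the bounds are swapped with a
  warning so the sampling interval stays valid.
- **One split per run.** Subjects are split once per run, not per
  survey (a per-repetition resplit happens in the comparison
  harness), matching the sequencing "random extraction, then the
  split" of the source; resampling is available by re-running with a
  different split seed.
- **Selection rule.** "Can be used as the final feature set" is
  operationalized as argmax validation accuracy with deterministic
  tie-breaks; no explicit acceptance criterion is stated.
- **Baseline feature mode.** The comparison models default to the
  RS-SVM-selected columns ("the same features were applied to the
  five models"); a mode using all retained voxels is available.

## Known limitations

- On fully continuous data the extremum tie counts almost surely
  degenerate to C_min = C_max = 2 (a unique closest and a unique
  farthest voxel pair), so surveys contain exactly two voxels. The
  published bounds (132/21) arise from ties that quantized,
  large-cohort group means produce; continuous synthetic means have
  none. Selection still works — a survey containing even one
  informative voxel wins validation — and selected surveys are
  dominated by planted voxels (precision ≥ ½ across seeds), but
  *recall* of a 40-voxel planted blob is structurally capped at
  l/40 = 0.05. A recovery criterion phrased as "recall ≥ 0.5" is
  unattainable in this regime and is reported as failing by design;
  precision is the meaningful recovery measure at these survey
  sizes.
- The SMO solver targets desk-scale problems (hundreds of subjects,
  survey-sized feature sets); it precomputes the full kernel matrix.
- Binary contrasts only; no multi-class support, no nested
  cross-validation, no probability calibration.
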