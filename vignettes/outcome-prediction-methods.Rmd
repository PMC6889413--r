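---
title: "Predicting treatment outcome from resting-state networks: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting treatment outcome from resting-state networks: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnpredict)
```

## The analysis problem

A cohort of patients undergoes trauma-focused psychotherapy; treatment
response is defined as a decrease of at least 30% in the total CAPS
(Clinician-Administered PTSD Scale) score between baseline and follow-up.
The question is whether *pre-treatment* resting-state fMRI carries enough
information to (a) detect group differences between eventual responders
and non-responders, and (b) predict the outcome for an individual
patient. `rsnpredict` implements the full analysis chain for this
question, together with a synthetic cohort generator that makes every
stage testable without patient data.

The chain is:

1. **Group network discovery** on an independent control group:
   temporal concatenation, PCA whitening, and spatial ICA by a symmetric
   fixed-point iteration; repeated runs are pooled and re-decomposed
   (*meta-ICA*) and components are labeled signal or noise by explicit,
   auditable heuristics.
2. **Dual regression**: stage 1 regresses each patient's scan on the
   group maps to get subject time courses; stage 2 regresses each
   voxel's time series on those time courses to get subject-specific
   network maps (the stage-2 betas are the features for everything
   downstream).
3. **Univariate inference**: a voxelwise GLM (group contrast with age,
   and TIV for structural maps, as covariates), TFCE enhancement, and
   family-wise error control by the permutation distribution of the
   maximum enhanced statistic pooled over *all* networks at once.
4. **Single-subject classification**: a probit Gaussian process
   classifier per network, evaluated by repeated stratified
   cross-validation with fully nested feature selection, label
   permutation significance with Bonferroni correction, reject-option
   curves, selection-stability cluster tables, and post-hoc
   cluster-network time-course correlations.
5. **Clinical statistics**: the demographic/clinical comparison battery
   (pooled t, uncorrected Pearson chi-square, Kruskal-Wallis, ANOVA),
   including a machine-readable fixture of the printed summary table and
   a reproduction report.

`run_pipeline()` executes stages 1-4 end to end from one seeded
configuration; all stage seeds derive deterministically from the run
seed, so any stage can be reproduced in isolation.

## The synthetic cohort generator

The generator (`sim_config()`, `simulate_cohort()`) implements the
linear spatial-mixing model that ICA and dual regression assume:
`scan(v, t) = sum_k loading_k tc_k(t) map_k(v) + noise`. Its defaults are
the study conditions of the motivating design:

* grid 20 x 24 x 20 voxels of 4 x 4 x 3.6 mm, 100 timepoints at
  TR = 1.6 s;
* 28 controls, 24 responders, 20 non-responders;
* d = 8 networks as unit-peak Gaussian blobs with 4-voxel FWHM, placed
  by seeded farthest-point sampling so centers are pairwise separated by
  at least twice the FWHM (pairwise map correlations < 0.2);
* per-subject network time courses: white Gaussian noise low-pass
  filtered at 0.1 Hz and standardized; loadings near 1 (SD 0.15);
* i.i.d. Gaussian scan noise with SD 1.0 relative to unit signal;
* clinical scores drawn consistently with the response rule (patient
  baseline CAPS ~ Normal(70, 13) truncated at >= 45, controls < 15;
  responders reduce by Uniform(0.35, 0.85), non-responders by
  Uniform(-0.10, 0.25); ages Normal(36, 9) clipped to 18-60; TIV
  Normal(1540, 140) ml);
* a group effect planted as a multiplicative amplitude change
  (`1 + effect_size`) of one network inside its half-maximum core for
  non-responders — the discriminative signal the pipeline must find;
* structural maps as smooth random fields with no group effect by
  default (the null structural finding).

What the generator deliberately does **not** emulate: physiological
noise and its temporal autocorrelation, motion artifacts, scanner drift,
registration error, and spatially correlated noise. Tests passing on
this model therefore validate the *estimation machinery* — that each
stage recovers what the model says it should, that null calibration and
error control hold, and that no information leaks across
cross-validation boundaries — not the physiological realism of real
rs-fMRI.

## Numerical and design choices

**Spatial ICA.** Voxels are the samples: whitening centers each row
(timepoint or stacked map) over voxels and projects onto the top-d PCA
subspace of the row covariance. The fixed-point iteration uses the tanh
contrast by default, symmetric decorrelation, convergence when the
rotation update falls below 1e-5 (maximum 300 iterations), and
non-convergence is flagged, never silent. Maps are z-scored over the
mask with the sign convention that the peak-|weight| voxel is positive.
Within-subject voxel time series are normalized by a successive-
difference noise-SD estimate (`sd(diff(x))/sqrt(2)`) before
concatenation — normalizing by total SD would flatten exactly the
spatial amplitude structure ICA uses.

**Meta-ICA.** Realized as re-decomposition of the stacked z-scored maps
of `n_meta_runs` (default 25) runs started from different random
rotations; a subject-bootstrap resampling of the concatenated blocks is
available behind a flag. Non-convergent runs are dropped from the stack;
more than half dropped is an error. A property worth knowing: on this
generator's i.i.d.-noise model, converged single runs are deterministic
up to solver tolerance — every initialization reaches the same fixed
point — so init-resampled meta-ICA reproduces the single-run solution
(matched ground-truth correlations agree to ~1e-7), and bootstrap
meta-ICA is slightly *worse* because each run sees fewer unique
subjects while the runs' errors remain correlated through the shared
data. Meta-ICA earns its keep on data whose runs genuinely vary; the
validation suite records the tie honestly rather than manufacturing a
win.

**Component labeling.** A component is noise if more than half of its
time-course spectral power lies above 0.1 Hz (a white-noise course at
TR 1.6 s puts ~68% of its power there) or if more than half of its
suprathreshold (|z| > 2) map weight lies on the mask boundary shell.
Both thresholds are explicit configuration; manual overrides are applied
last and recorded, which is what makes a "semi-automatic" procedure
auditable.

**Dual regression.** Stage 1 includes an explicit spatial intercept;
scans are voxelwise demeaned, so betas are fluctuation amplitudes.
Stage 2 variance-normalizes the stage-1 time courses by default, making
betas connectivity-amplitude-like; with normalization on, scaling a
subject's scan by c scales its stage-2 betas by c exactly. On noiseless
rank-d cohorts the stage-2 betas reproduce the ground-truth maps to
|r| > 0.999 — the exactness oracle for the whole two-stage chain.

**TFCE and permutation FWE.** TFCE uses E = 0.5, H = 2,
26-connectivity, and 100 integration steps (`dh = max/100`), the cited
method's volumetric defaults. The implementation processes thresholds
descending with incremental cluster merging (each voxel activated once),
which is algebraically identical to naive per-threshold relabeling — the
test suite proves equality to 1e-8 against a brute-force oracle — at a
fraction of the cost. Two-tailed inference enhances the positive and
negated maps separately and takes the voxelwise maximum, applying the
same rule to observed and permuted data, so no post-hoc doubling of p
values is needed. Covariates are respected by Freedman-Lane residual
permutation (permute reduced-model residuals, add back the nuisance
fit, refit); simple row permutation is available behind a flag. The
null is the per-permutation maximum enhanced statistic over all voxels
of all families jointly, the observed data count as one permutation,
and the smallest attainable p is `1/(n_perm + 1)`.

**Gaussian process classifier.** Linear kernel
`k(x, x') = sigma_f^2 (x . x')/p + sigma_b^2` on per-feature
standardized inputs (standard when features vastly outnumber subjects;
RBF available), probit likelihood, Laplace approximation with Newton
iteration to the latent mode (objective tolerance 1e-6, at most 100
iterations, deterministic), and hyperparameters chosen by the Laplace
evidence over a fixed 5 x 5 log-spaced grid on [0.1, 10]. A dense
quadrature oracle over the whitened latent space bounds the
approximation error: predictive probabilities agree within 0.03 at
weak-to-moderate prior amplitude (sigma_f <= 0.8, the regime the
validation suite pins down), and the agreement degrades as the prior
amplitude grows — the known conservatism of Laplace relative to EP. EP
would be the upgrade path if calibrated probabilities at large
amplitude mattered; for the reject-option analysis here, what matters
is the ranking and approximate centering of the probabilities, which
Laplace preserves.

**Cross-validation protocol.** Ten-times repeated stratified 10-fold by
default; within every outer training fold, the retained-feature count k
is tuned by an inner stratified 5-fold loop over
{100, 250, 500, 1000, 2000} (capped at the feature count), re-ranking
features by |two-sample t| on each inner training set. Standardization
and selection structurally never see test rows, and the suite contains
a regression test showing what leakage would do: selecting features on
the full data before CV lifts null-data accuracy to ~0.98 while the
shipped pipeline stays at chance. Metrics (balanced accuracy,
sensitivity, specificity, Mann-Whitney AUC, PPV, NPV) are computed per
fold and aggregated as mean +- SD over all repeats x folds; folds with
an empty confusion-matrix denominator are recorded missing for that
metric only. Label-permutation significance reruns the entire nested
pipeline per permutation (1 CV repeat per permutation by default, for
tractability at 1000 permutations; configurable to full fidelity), and
the Bonferroni multiplier defaults to n_networks + 1, counting the
structural analysis as one more test. The reject-option curve excludes,
per repeat, subjects whose out-of-fold probability falls inside
(0.5 - u/2, 0.5 + u/2) — u = 0.10 rejects the 45-55% band — and
averages retained balanced accuracy across repeats.

**Clinical statistics.** Pearson chi-square is computed *without*
continuity correction — the variant that reproduces the printed 2 x 2
statistics from their count tables. The pooled t's sign follows
`mean2 - mean1`, with the fixture recording per row which group order
yields the printed sign (the printed table is not internally consistent
about it). Twelve printed statistics reproduce within 1e-3 (the
count-based rows exactly at 3 decimals; the summary-moment rows are
limited by the 2-dp rounding of the printed means). Rows whose printed
values match no standard formula — all post-treatment chi-squares and
two rows with unknown denominators — are reported as non-reproducible
with their differences, never force-fitted.

## Validation at desk scale

The acceptance suite (`tests/testthat/test-acceptance.R`, recomputable
via `scripts/acceptance.R`) runs the whole battery at problem sizes
chosen so the full suite completes in minutes on one core; these sizes
are part of the package's validation design:

* dual-regression exactness on noiseless 10^3-voxel cohorts;
* meta-ICA vs single-run ground-truth recovery over 10 generator seeds
  (16 x 16 x 12 grid, 8 controls, 8 meta runs, noise SD 1.2);
* TFCE fast-vs-brute equality on 20 random 10^3 maps and the
  hand-computed single-voxel case (enhanced value 3.75 at h = 2,
  dh = 0.5);
* family-wise error calibration: 200 null cohorts, 4 networks pooled,
  199 permutations — the realized FWE rate must lie in [0.02, 0.09]
  at alpha = 0.05;
* GPC Laplace-vs-quadrature agreement within 0.03 on 20 tiny problems;
* null classification calibration (mean balanced accuracy over 10 null
  cohorts in [0.40, 0.60]; permutation p values with mean in
  [0.3, 0.7] over 12 null cohorts at 99 permutations);
* planted-effect recovery at effect size 1.6 with 24 vs 20 patients:
  balanced accuracy >= 0.75 and the planted network ranked first among
  all networks;
* reject-option curves nondecreasing in the uncertainty width over 10
  seeds, with the u = 0 point equal to the overall accuracy exactly.

## Known limitations

* The generator's i.i.d. noise makes ICA easier (and meta-ICA less
  necessary) than on real data; temporal autocorrelation and structured
  artifacts are out of scope.
* Laplace predictive probabilities are conservative at large prior
  amplitude (see above); EP is the alternative if that regime matters.
* The component-labeling heuristics are a documented stand-in for
  expert review; on real data the override mechanism is the expected
  workflow.
* Printed-table reproduction can only be as precise as the printed
  inputs; rows with unreported missing data stay non-reproducible by
  design.
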