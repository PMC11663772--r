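---
title: "Multi-modal MRI classification of depression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal MRI classification of depression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddfusion)
```

# The problem

Major depressive disorder (MDD) is diagnosed, and its treatment monitored,
through clinical interviews such as the 17-item Hamilton Depression Rating
Scale (HDRS, range 0--52). `mddfusion` implements a complete machine-learning
pipeline for two binary questions asked of multi-modal MRI data:

* **Diagnosis** -- distinguish MDD patients from healthy controls (HC);
* **Outcome** -- predict, from baseline imaging, whether a patient will reach
  a *positive outcome* (PO) at 6-month follow-up, defined as a relative HDRS
  reduction of at least 50% (`label_outcome()`, boundary inclusive; patients
  below the threshold are negative outcome, NO).

Each subject is described by eleven tabular *feature sets* derived from four
MRI modalities: T1 volumes and cortical thickness, T2 hippocampal/amygdalar
subfield volumes, five diffusion (DTI) edge-metric sets (MD, FA, AD, RD and
streamline weights, one value per unique connection among 84 regions, so
`choose(84, 2) = 3486` elements each), task-activation contrasts, and three
resting-state network-interaction sets computed by this package from 15
network time series: static functional connectivity (sFC, 105 elements),
number of coherence clusters (nCC, 105) and lead coherence (leadCoh, 210
directed elements). Because cohorts of this kind cannot be shared, the
package ships a synthetic-cohort module that reproduces the *statistical
structure* of such data, and every stage is exercised end-to-end on it.

# Wavelet-coherence network interactions

Static FC is the Fisher z-transformed Pearson correlation per unordered
network pair (correlations capped at `1 - 1e-6` before `atanh` so
self-similar series stay finite). The two dynamic features come from
wavelet coherence analysis (WCA). For a pair of series, `wavelet_coherence()`
computes Morlet continuous wavelet transforms (central frequency
$\omega_0 = 6$) on a geometric scale grid spanning the fMRI band-pass
window 0.01--0.2 Hz (1/8-octave steps), then forms the magnitude-squared
coherence from scale-normalised auto- and cross-spectra smoothed in time
(Gaussian of width equal to the scale) and across scales (0.6-octave
boxcar). Cells closer to an edge than the e-folding time $\sqrt{2}s$ lie
outside the cone of influence and are excluded. The *significance mask* is
a fixed coherence cutoff (default 0.7) inside the cone; the upstream
parameterisation of this rule is not fully specified in the literature the
design follows, so both the cutoff and the scale range are exposed as
arguments and the defaults above are used throughout the tests.

* **nCC** counts the 4-neighbour connected components of significant cells,
  with components split by phase category -- in-phase ($|\varphi| < \pi/4$),
  out-of-phase ($|\varphi| > 3\pi/4$), leading and lagging (the two
  intermediate quadrants by sign) -- i.e. the number of distinct coherent
  interactions between two networks over the scan.
* **leadCoh** is directed: for the ordered pair $i \to j$ it is the fraction
  of significant cells in which $i$ leads in phase ($\varphi > 0$). Whether
  a binary lead indicator or a phase-weighted extent is aggregated is an
  open design choice; both are implemented (`lead_coherence(mode =)`), with
  the binary fraction as default. Swapping the pair negates the phase, so
  `leadCoh` is asymmetric while coherence magnitude is not.

A useful internal check: the whole coherence estimator is exactly
mirror-symmetric under joint time reversal of both series, and the test
suite asserts bit-level invariance of nCC under reversal (this invariant
caught a half-kernel misalignment in the smoothing convolution during
development).

# Classification: double ranking inside nested leave-one-out CV

With at most 63 subjects and up to 3486 elements, feature selection must be
aggressive and scrupulously leakage-free. `run_nested_loocv()` implements:

1. **Outer loop**: leave one subject out; everything below sees only the
   `n - 1` training subjects.
2. **Univariate screen**: per element, Shapiro--Wilk normality in each class
   at $\alpha = 0.05$ decides between a pooled two-sample t-test and a
   Wilcoxon rank-sum test; the `k_initial` smallest p-values survive (ties:
   larger $|$statistic$|$, then element index). `k_initial = "All"` disables
   truncation. With fewer than 3 subjects in a class the gate is skipped and
   the rank-sum test used (flagged).
3. **Final ranking**: either MRMR or CV-SVM (below) orders the survivors.
4. **Inner loop**: a second leave-one-out over the training subjects re-runs
   the *entire* double ranking per inner fold and fits a linear SVM on each
   nested prefix of size $1..k_{final}$. Each inner fold contributes one
   held-out decision value per candidate size; pooling them gives one
   validation AUC per $k$, and `k_optimal` is the smallest $k$ attaining the
   maximum. (An "averaged over inner folds" variant is not provided: an
   inner LOO fold yields a single decision value, so a per-fold AUC does
   not exist -- pooling is the only well-defined reading.)
5. **Outer model**: the double ranking is recomputed on the full training
   fold, a linear SVM with the top `k_optimal` elements is fit, and the
   held-out subject is predicted.

Features are z-scored per fit with training-fold statistics (SVMs are scale
sensitive; the held-out subject is standardized with the *training* mean
and SD). The SVM cost is fixed at $C = 1$ and never tuned -- the number of
features is deliberately the only optimized quantity. The solver is a
compact SMO implementation of the linear C-SVC compiled in `src/` (the
per-fit call overhead of general-purpose SVM wrappers dominates at these
problem sizes); the test suite verifies its hyperplanes against libsvm via
`e1071` to $5\times10^{-3}$.

Reported metrics (`compute_metrics()`): AUC by Mann--Whitney pair counting
with ties counting 1/2, accuracy, sensitivity, specificity, precision and
F1 (the latter two defined as 0 when their denominator vanishes). The
reference operating point for the ranking sizes is `k_initial = 10`,
`k_final = 5`.

## MRMR

Greedy forward selection maximizing relevance minus mean redundancy. The
formulation is stated in terms of mutual information; for continuous
features with a binary class at small n, the package uses the standard
continuous surrogate -- but on a common scale: relevance is the one-way F
statistic mapped to its equivalent point-biserial correlation,
$r = \sqrt{F / (F + n - 2)}$, and redundancy is the mean absolute Pearson
correlation with the already-chosen set. Keeping both terms in $[0, 1]$ is
what makes the difference form behave: an exact duplicate of a chosen
element (redundancy 1) can never outrank an independent noise element,
which an unbounded F-statistic relevance would allow. Determinism: ties
break by column index. The greedy ordering is verified against an
independently coded oracle in the tests.

## CV-SVM (feature selection via concave minimization)

The sparse-plane program minimizes a weighted sum of average
misclassification distances from two bounding planes and a concave penalty
$\sum_i (1 - e^{-\alpha v_i})$ on bounds $v_i \ge |w_i|$, with defaults
$\alpha = 5$, error/sparsity trade-off $\lambda = 0.2$, at most 50
successive linearization steps, and convergence declared when the weight
support is unchanged and the objective improves by less than $10^{-6}$.
Each linearization step is a linear program solved by an internal two-phase
primal simplex with Bland's rule (deterministic and finite; the only LP
solver available in the package's dependency set proved numerically
unreliable on these degenerate programs). If a step fails, the previous
iterate is returned flagged, as is the ordering at the iteration cap.
Elements are ranked by $|w|$ of the final plane; zero-weight elements
follow, ordered by univariate p-value -- so with no signal at all the
ranking degrades gracefully to the univariate one.

# Multi-modal fusion

Three strategies, mirroring the reference workflow:

* **Concatenation** (`concatenate_sets()`): all sets side by side, then the
  uni-modal procedure unchanged. Sets are never silently reordered; a
  subject-order mismatch is an error.
* **Forced fusion** (`run_forced_fusion()`): inside *every* training fold,
  each set contributes its univariate top-5 elements; the pooled columns
  then enter the usual final ranking and nested search with
  `k_final = 5`. Whether the original design re-optimized $k$ up to 5 or
  always used exactly 5 is ambiguous; this package runs the full search
  ($k = 1..5$), the more conservative reading.
* **Majority-vote ensembles** (`ensemble_performance()`): the stored
  uni-modal outer-fold predictions are fused by majority vote over odd-size
  member subsets (`n_set` in {3, 5, 7, 9} or all eleven); no refitting.
  Because fused output is a binary label, the ensemble "AUC" is the
  single-point ROC value, identical to (sensitivity + specificity)/2 --
  the tests assert this equality rather than pretending a continuous score
  exists. Even member counts arise only during ablation; ties then break by
  the sign of the summed decision values (logged).

# Inference

* **Permutation test** (`permutation_test()`): class labels are shuffled
  (simple shuffle -- the class ratio is preserved by construction) and the
  *entire* nested pipeline re-run per permutation;
  $p = \#\{\mathrm{AUC}_{null} \ge \mathrm{AUC}_{true}\} / n_{perm}$, ties
  counting against the hypothesis. The reference protocol uses 1000
  permutations; a count of 0 yields $p = 0$, printed as
  $< 1/n_{perm}$.
* **Bootstrap CI** (`bootstrap_auc_ci()`): subjects' (decision value,
  label) pairs are resampled with replacement to the original n -- the
  predictions are fixed, no refitting -- and the 2.5/97.5 percentiles of
  the resampled AUCs form the 95% CI. Resamples missing a class are
  redrawn and counted.
* **Group screen** (`group_difference_screen()`): the same normality-gated
  univariate test per element, with Benjamini--Hochberg FDR at
  $\alpha = 0.05$ applied *within each feature set separately* (the
  correction scope follows the reference design).

Reproducibility across all resampling: one master seed expands into
per-stage, per-replicate child seeds through a counter-based integer hash
(`child_seed()`), so replicates are independent of execution order.

# Feature analysis

`outer_fold_contribution()` reports, per element, the percentage of outer
folds whose model contained it and its mean $|\beta|$ over those folds
(weights live in standardized-feature space, hence comparable);
`beta_impact()` re-sorts by the latter -- the two views can legitimately
disagree and both are always reported. `normalize_contributions()` rescales
contributions onto $[0, 1]$ by the pooled min/max across models.
`ablate_ensemble()` removes one member at a time from a fused ensemble and
reports the AUC drop; negative drops (removal helps) are reported, not
suppressed.

# The synthetic cohort generator

`synthetic_spec()` + `generate_feature_tables()` produce two-group feature
tables with unit-variance Gaussian marginals, optional equicorrelation
$\rho$ within a set (one shared factor per subject), and planted
standardized mean differences $d$ on chosen elements -- exactly the
mean-shift structure the univariate t/rank-sum gate assumes, while staying
analytically tractable. `generate_rsn_timeseries()` builds network series
as white noise plus shared narrow-band (Gaussian band-filtered) components
per coupled pair; the copy in the second network is delayed by an exact FFT
time shift, so a pair couples at a chosen frequency with a chosen phase
lag, and uncoupled networks are independent. `generate_hdrs()` draws
baselines from the configured severity distribution (default mean 24.4, SD
4.62), relative reductions from truncated normals per assigned outcome
group, rounds to the integer instrument and clips to [0, 52]; where
rounding would flip a label across the 50% boundary the follow-up is
nudged by one point, so at label-noise 0 the outcome labels recover the
assignment exactly (noise is injected explicitly, never by accident).

What the generator does *not* emulate: site/scanner effects, heavy-tailed
or skewed feature marginals, realistic anatomical covariance beyond
equicorrelation, age/sex structure, and 1/f temporal spectra. Passing
tests therefore demonstrate correctness and calibration of the *pipeline*,
not expected performance on clinical data.

# Numerical and design choices

* Element order is fixed everywhere by a canonical node ordering
  (row-major upper triangle; directed pairs row-major with $i \ne j$), so
  element indices are comparable across runs.
* The Shapiro--Wilk gate uses a vectorised implementation of Royston's
  approximation (validated against `stats::shapiro.test` to $10^{-6}$);
  the Wilcoxon gate uses the normal approximation with tie and continuity
  corrections (matching `wilcox.test(exact = FALSE)`); the screen is also
  compiled in `src/` with the R composition kept as the reference route in
  the tests.
* Ties: p-value, then $|$statistic$|$, then element index (ranking);
  smallest $k$ (inner argmax); column index (MRMR); summed decision values
  (even-vote ablation).
* Degenerate inputs: constant elements get t = 0 / p = 1 and rank last;
  constant channels are an error for sFC; an inner fold left with one
  class is skipped and counted; a bootstrap resample missing a class is
  redrawn.
* Problem sizes in the test suite and the `analysis/` scripts (e.g.
  20 + 20 subjects with 105 elements for calibration, 200 permutations,
  8-network time series in the demo workflow) were chosen as the smallest
  cohorts at which the respective property is statistically decidable;
  the reference protocol values (1000 permutations, 1000 bootstrap
  resamples, 15 networks, full set sizes) remain the defaults or explicit
  arguments.

# Known limitations

* The exact WCA parameterisation of the work this design descends from is
  not public; the defaults here are anchored to the 0.01--0.2 Hz band and
  a fixed coherence cutoff, and nCC/leadCoh values will shift under other
  choices (the element counts and invariances will not).
* LOOCV test AUC on null data is biased slightly below 0.5 (the familiar
  anti-learning effect of selection inside small LOO folds); the null
  calibration band in the acceptance suite accounts for this.
* The permutation test re-runs the full pipeline and is therefore
  expensive by design; scale `n_perm` to your budget.
* No covariate adjustment (age, sex), no kernels beyond linear, no
  probability calibration, no stacking -- matching the scope of the design
  this package implements.
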