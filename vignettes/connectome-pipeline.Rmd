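---
title: "Structural connectomics from diffusion phantoms to group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural connectomics from diffusion phantoms to group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factconn)
```

## The problem

Parkinson's disease (PD) and SWEDD ("scans without evidence of dopaminergic
deficit") present with similar motor symptoms but require different
management, so markers that separate the two groups are clinically valuable.
One candidate marker family is structural connectivity: the number of
white-matter fibers connecting pairs of motor-related brain regions,
estimated from diffusion tensor imaging (DTI) by deterministic tractography.
`factconn` implements that analysis chain end to end — tensor estimation,
FACT streamline tracking, fiber-count connectome construction, edge-wise
permutation testing, clinical-score correlation screening, and leave-one-out
cross-validated (LOOCV) linear SVM classification — together with synthetic
diffusion phantoms and synthetic cohorts so that every stage can be validated
against known ground truth. Real cohort data of this kind live in
access-controlled archives; the synthetic generators stand in for them and
are first-class, tested code.

## Signal model and tensor estimation

Each voxel's diffusion is modeled as a symmetric positive semi-definite
$3 \times 3$ tensor $D$ (mm²/s). A measurement with b-value $b$ (s/mm²) and
unit gradient direction $g$ follows the Stejskal–Tanner monoexponential
model

$$S = S_0 \exp(-b\, g^\top D g).$$

The default acquisition (`default_scheme()`) is one $b=0$ image plus 64
directions at $b = 1000$ s/mm², a standard clinical single-shell protocol.
Directions are placed on a spherical Fibonacci lattice: deterministic,
near-uniform, and well-conditioned for the 6-parameter fit.

`fit_tensor_loglinear()` estimates $D$ by log-linear least squares:
$\ln(S/S_0) = -b\,g^\top D g$ solved over the six unique components, with
$S_0$ the mean of the $b=0$ measurements. The estimator is deliberately the
plain unweighted log-linear fit — closed-form, deterministic, and accurate at
the signal-to-noise ratios the phantoms use (relative error $<10^{-6}$
noiseless; median principal-direction error well under 5° at SNR 20).
Weighted or nonlinear estimators would reduce noise sensitivity at low SNR
but add iteration and tie the result to solver settings; the fit is isolated
behind one function so it can be swapped. Numerical guards: signals are
floored at $10^{-6} S_0$ before the log; negative eigenvalues are clamped to
0 and the voxel flagged `clamped`; a near-degenerate leading eigenpair
($|\lambda_1-\lambda_2| < 10^{-12}$) keeps the decomposition's first vector,
is flagged `low_confidence`, and is treated by tracking like any valid voxel
— rejection would punch holes in isotropic regions where the direction is
arbitrary but harmless.

Noise uses the Rician magnitude model: each measurement is replaced by
$|S + \eta_1 + i\eta_2|$ with $\eta_{1,2} \sim N(0, \sigma^2)$,
$\sigma = S_0/\mathrm{snr}$. This reproduces the positive signal floor of
magnitude MRI (the mean of a noisy zero signal is $\sigma\sqrt{\pi/2}$, not
zero).

## FACT tractography

`track_fact()` implements fiber assignment by continuous tracking: from the
center of every seed voxel, a line is propagated along the principal
eigenvector, advancing each step to the exact exit point of the current
voxel (ray–box intersection) and adopting the next voxel's eigenvector
there. Termination occurs when the next voxel is outside the tracking mask
or grid, is invalid, or when the direction change exceeds the angle
threshold (default 60°, the conventional abrupt-turn criterion: 60° itself
continues, anything greater stops).

Design choices that the classical FACT description leaves open, and how this
implementation resolves them:

* **Bidirectional launch.** Two half-tracks leave the seed center along
  $+e_1$ and $-e_1$ and are concatenated. Without this a fiber could only
  reach one of its two endpoint regions from an interior seed.
* **Sign disambiguation.** Eigenvectors are sign-ambiguous; the candidate
  direction is flipped when its dot product with the incoming direction is
  negative, so the angle test always compares directions on the same
  hemisphere.
* **Boundary stepping.** True voxel-boundary intercept stepping rather than
  a fixed step length; corner and edge hits are resolved by nudging the exit
  point `step_epsilon` ($10^{-4}$ voxels) along the current direction, which
  selects a unique next voxel deterministically.
* **"White matter and its neighbors."** The tracking mask is the seed mask
  dilated by one voxel with 26-connectivity (`mask_dilation_voxels = 1`);
  seeds are the undilated mask voxels.
* **Coordinates.** All tracking runs in continuous voxel space where voxel
  $(i,j,k)$ (1-based) spans $[i-1,i)\times[j-1,j)\times[k-1,k)$; world
  coordinates appear only at export (TRK writes voxel-mm).

Tracking contains no randomness: identical inputs give bit-identical
streamlines.

## Fiber-count connectomes

A streamline contributes to edge $(A,B)$ when the labels of its two terminal
voxels are the distinct nonzero regions $A$ and $B$; background endpoints
and within-region loops drop the fiber (the connectivity matrix is used
strictly between distinct regions). Endpoint lookup is the label of the
terminal voxel itself — no neighborhood search — which is the simplest
reading of "endpoints residing within two ROIs". Entries with fewer than
`min_fibers = 5` fibers are zeroed; a count of exactly 5 is retained, since
only "fewer than 5" is treated as tractography instability. The filter is
applied per subject, at matrix construction, because that is where sparse
counts arise. The packaged region table (`motor_regions()`) has 39 entries:
19 bilateral motor-related structures plus the brainstem, ordered left/right
per structure, and that order fixes matrix rows for all subjects.

## Phantom geometry

`make_bundle_phantom()` supports straight bundles and sharp-corner polylines
("bends"), with analytic per-segment tangents. A sharp 90° corner is what
exercises the angle-threshold rule — a gradual arc of the same total turning
would be crossed happily because the per-voxel direction change stays small
— so the bend primitive replaces an arc primitive in this version. Bundle
voxels are those whose centers lie within half the cross-section width of
the segment axis; each gets the anisotropic tensor
$(\lambda_{ax}-\lambda_r)\,tt^\top + \lambda_r I$ oriented along the local
tangent (defaults $1.5\times10^{-3}$ / $0.3\times10^{-3}$ mm²/s, FA ≈ 0.77,
against an isotropic background of $0.7\times10^{-3}$ mm²/s). Endpoint label
blocks cover the bundle cross-section from 1.5 voxels inside to 2.5 voxels
beyond each end, so a track that stops at the last bundle voxel or coasts
one voxel into the dilated mask lands in a labeled voxel either way. On a
straight bundle of $W$ voxels this makes the recovered edge weight exactly
$W$ — the property the phantom tests pin down. Overlapping bundles with
conflicting orientations are refused (single-tensor voxels cannot represent
crossings); crossing geometries must use disjoint voxel sets.

## Synthetic cohorts

`make_cohort()` draws per-subject edge counts from a negative binomial
distribution, matching the strong overdispersion of published fiber-count
tables, where standard deviations run from roughly half the mean to above
it. The default size (dispersion) parameter 2 reproduces that
coefficient-of-variation pattern at the default baseline mean of 20 fibers
(CV ≈ 0.74). Group-B means are shifted multiplicatively at planted effect
edges; published significant edges show group ratios of roughly 2–4, and the
demonstration cohort (`demo_cohort_spec()`) plants a ratio of 4 at four
motor-circuit edges. All four planted effects are increases with a common
baseline: the permutation correction uses the maximum of raw mean
differences across edges, and that statistic assumes comparable edge scales
— planting large effects in both directions at a common baseline would let
the inflated-variance edges dominate the permutation null and mask the
smaller-scale ones. The clinical score is
$\mathrm{round}(\beta_0 + \sum_e s_e w_e + N(0,\sigma))$ floored at 0 —
integer-valued like an ordinal motor sum-score. The demonstration defaults
($\beta_0 = 10$, slopes 0.04, $\sigma = 2$) give a score distribution with
mean ≈ 18 and SD ≈ 6.5, in the range reported for de novo PD cohorts, and a
pooled edge–score Spearman correlation of ≈ 0.65–0.75 at the planted edges,
slightly above the 0.54–0.56 reported on real data so that joint recovery of
all four edges is reliable across seeds. What the generator does *not*
emulate: spatial correlation between edges, site effects, age/sex structure,
and registration/segmentation error. Passing tests therefore demonstrate
the correctness of the statistical machinery under the stated model, not
robustness to those real-data features.

## Group statistics

`permutation_group_test()` uses the signed difference of group means per
edge, permutes group assignments (default 10,000 reassignments at the fixed
group sizes), and reports two-sided p values with the add-one estimator
$p = (1 + \#\{|T_{perm}| \ge |T_{obs}|\})/(B+1)$ — never exactly zero, and
valid by construction. Two-sided testing reflects that group differences
occur in both directions. The "corrected" p value is the single-step
max-statistic family-wise error rate: the permutation distribution of
$\max_e |T_{perm}(e)|$ over the tested family, which is self-contained
(derived from the same permutation null, in the spirit of a 95th-percentile
null criterion) and exact under exchangeability. Uncorrected p values are
reported alongside, so a per-edge reading is also available. Edges that are
zero in every subject are untestable and excluded. An exhaustive mode
enumerates all $\binom{n}{n_A}$ assignments for small cohorts and is the
internal oracle for the Monte-Carlo estimator.

`correlate_edges_with_scores()` pools all subjects of both groups per edge,
computes Spearman's rank correlation (average ranks for ties — appropriate
because the score is ordinal), converts to p via the large-sample t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (comfortable at $n = 77$),
and applies the Holm–Bonferroni step-down over the tested family with the
conventional reporting threshold of adjusted $p \le 0.001$. Constant edges
are flagged and excluded from the family rather than erroring the screen.

## Classification

`loocv_linear_svm()` holds out each subject once, standardizes features
with the *training* fold's mean and SD (avoiding test-set leakage at the
scaling step; an SD of zero falls back to 1), trains a linear-kernel SVM
(cost default 1.0 — unstated in typical protocol descriptions, so exposed
as a parameter), and predicts the held-out subject. Feature selection (the
edges passing both screens) happens once on the full cohort before the
cross-validation loop, mirroring the published protocol; note this is
optimistically biased, since the held-out subject contributed to the
selection — the run report records the selected edges so the protocol is
auditable. The positive class for sensitivity defaults to the first group
level (SWEDD in the packaged cohorts), the assignment under which the
published 78.38% sensitivity equals 29/37 exactly. Accuracy always equals
the prevalence-weighted mean of sensitivity and specificity, which the
report checks.

## Problem sizes and numerical conventions

The test and validation suites use: phantoms of ~50–1100 bundle voxels on
grids up to $62^3$-equivalent; cohorts of 37 + 40 subjects over 39 regions
(741 edges); 10,000 permutations for single cohorts and the planted-recovery
suite (50 seeds), 2,000 for the 200-cohort null-calibration suite, where the
only question is whether a corrected p crosses 0.05 and coarser resolution
suffices. Permutation comparisons use a relative tolerance of $10^{-9}$ when
counting $|T_{perm}| \ge |T_{obs}|$ so that exact ties (e.g. the identity
assignment) are never lost to floating-point noise. All randomness flows
from user-supplied seeds through derived per-stage seeds; RNG state is
restored after every call.

## A worked run

```{r demo, eval = FALSE}
library(factconn)
report <- run_pipeline(pipeline_config(
  cohort = demo_cohort_spec(seed = 42), seed = 42))
report
tidy(report$permutation)      # per-edge permutation statistics
significant_edges(report$correlation)
glance(report$loocv)          # confusion counts and percentages
autoplot(report$permutation)  # -log10 corrected p per edge
```

## Known limitations

Single-tensor voxels cannot represent crossing or kissing fibers, so the
tractography inherits the classical FACT failure modes; no HARDI/ODF
support. No registration, segmentation, or eddy/motion correction — the
pipeline expects coregistered labels and masks (or phantoms). The
correlation screen's t approximation is asymptotic; for very small cohorts
an exact permutation of the score ranks would be preferable. The
max-statistic correction assumes comparable edge scales, which holds for
the packaged generator but should be checked (e.g. via variance
diagnostics) before applying raw-difference max-statistics to strongly
heteroscedastic data.
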