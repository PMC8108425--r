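---
title: "Quantitative signal from clinical MRI: bivariate histogram standardization and GMM tissue parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative signal from clinical MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical T1-weighted and FLAIR brain images are reconstructed in arbitrary
scanner units: the same tissue can map to very different intensities across
scanners, sites and sequence settings. That makes raw intensities useless as
quantitative biomarkers, even though T1 and T2 relaxation — which those
intensities encode approximately linearly — carry real information about
tissue microstructure, and in multiple sclerosis in particular about diffuse
damage in normal-appearing white matter (NAWM) that lesion counts miss.

`histnorm` standardizes the intensities instead of the physics. Each subject
contributes a bivariate histogram of paired (T1w, FLAIR) in-brain voxel
intensities; tissue classes (CSF, GM, WM, lesions) appear as modes of that
2D distribution. An affine map of the intensity plane is fitted that brings
the subject's histogram onto a normative reference built from a control
cohort, and that map is applied voxelwise. After standardization, tissue
statistics are comparable across subjects, and a small set of per-subject
Gaussian mixture parameters — the mean mu and standard deviation sigma of
the GM and WM components on each contrast, eight values in all — become
usable biomarkers. A statistical battery (group ANOVA with post-hoc
contrasts, ROC, Z-scored regressions against disability, PCA composites,
LASSO with hold-out) relates them to clinical status.

The package assumes spatially preprocessed inputs: co-registered,
brain-extracted, bias-field-corrected volume pairs with a brain mask. It
validates shapes but never resamples; spatial preprocessing is a separate
concern. Whether FLAIR was resampled to T1w space or vice versa is
deliberately left to the upstream pipeline.

## The reference atlas

Controls are histogrammed on a common binning: 256 x 256 bins per default,
with the range per contrast frozen at `[0, headroom x P99.9]` of the pooled
control intensities (`robustBinning()`). The headroom factor (default 2)
exists because subjects arrive in arbitrary scanner units: a range clipped
at the control upper percentile would truncate any subject whose scanner
scale runs hotter than the controls', and truncation corrupts precisely the
registration step the binning serves. Once built, the binning is frozen:
every subject is histogrammed on the atlas grid.

The reference is the arithmetic mean of the normalized control histograms,
so each control contributes equally regardless of brain size. A mean (not a
median or a single template) is the simplest estimator consistent with a
"normative" reference; the choice matters little for smooth unimodal class
modes. CSF/GM/WM centroid loci are found by hill-climbing on the
Gaussian-smoothed (sigma = 2 bins) reference from seed loci at the
normative peaks (T1w roughly 200/600/1000 for CSF/GM/WM; FLAIR roughly
200/700/1100 for CSF/WM/GM, in control scanner units). Lesions have no
control mode, so the LESION locus is constructed from geometry: T1w at the
GM/WM midpoint (lesions show intermediate T1 hypointensity), FLAIR at the
GM locus plus 1.5 x the GM-WM FLAIR gap (distinctly hyperintense). Both are
overridable. Centroid ordering constraints (T1: CSF < GM < WM; FLAIR:
CSF < WM < GM; lesion above WM on FLAIR) are enforced at construction; a
control set that violates them is pathological and refused.

## Histogram registration

The registration objective is a Hellinger-flavored sum of squared
differences: both histograms are normalized, smoothed with a separable
Gaussian (sigma = 2 bins), and square-root transformed; the subject
histogram is pushed through the candidate affine with bilinear
interpolation and a 1/det(A) Jacobian correction so probability mass is
conserved. The square root damps the dominance of the tall CSF/WM peaks so
the GM structure influences the fit; the smoothing makes the landscape
differentiable enough for a simplex optimizer.

The transform is a full 6-parameter 2D affine. Optimization is
derivative-free Nelder-Mead from five fixed starts (identity and +/-10
percent single-axis scalings), with offsets parameterized in bin widths so
all six parameters are on comparable scales. A coarse-to-fine pyramid
(factor 4) runs every start on a downsampled histogram and refines the best
at full resolution; the raw starts are always candidates too, so
self-registration returns the exact identity and the final error never
exceeds the error at any initialization. Iteration cap 2000 and relative
tolerance 1e-8 on the functional; there is no randomness anywhere, so
registration is bit-reproducible.

The functional value at the optimum is the subject's alignment error. A
fixed criterion separates usable from unusable alignments; since the
original criterion of this design is a visually chosen constant,
`qcGate()` offers a reproducible surrogate — median + 4 x MAD over the
batch — with the threshold always numerically overridable. Subjects
failing QC are excluded from group statistics but still emit parameters,
flagged.

## Segmentation and the conservative lesion rule

Voxels of the standardized pair are classified by a k-means-like iteration
in the intensity plane, initialized at the atlas centroids, with distance
measured after dividing each axis by its bin width (otherwise the
wider-range contrast dominates). The CSF/GM/WM centroids update from the
assignments; the LESION centroid stays frozen at the atlas prior, because
lesions are rare or absent in many subjects and a free lesion centroid
collapses onto WM. Ties break toward the lower class code. Convergence is
declared at 1e-3 bin widths of centroid motion, cap 100 iterations.

After convergence, a conservative rule reassigns ambiguous hyperintense
voxels to the lesion class: a voxel is relabeled LESION when its FLAIR
intensity exceeds the WM centroid by more than `flairMarginFrac` (default
0.5) of the WM-to-LESION FLAIR gap AND its nearest/second-nearest centroid
distance ratio exceeds `ambiguityRatio` (default 0.8). Both margins are
exposed configuration; lowering either is more conservative (more voxels
leave the normal-appearing pool), and the lesion count is monotone in that
direction — a property the tests assert. Classification is intensity-only
by default; an optional connected-component filter (26-connectivity,
minimum size) exists behind a flag but is off, since the method is
deliberately a statistical, not spatial, classifier.

Lesion burden is summarized two ways: volume (voxel count x voxel volume)
and the mean lesion intensity score u_lv, where the per-voxel score u_l is
the FLAIR elevation above the converged WM centroid in units of the
WM-to-LESION centroid gap, clipped at zero. The score is a dimensionless
"how far toward florid lesion intensity" measure: voxels at the lesion
locus score 1 by construction.

## GMM parameters and the lesion-inclusion variant

Per contrast, a three-component Gaussian mixture (CSF + the two analyzed
classes) is fitted to the pooled in-scope standardized intensities by EM,
seeded at the atlas loci with per-class SDs and label fractions from the
segmentation. Seeding from the atlas — never randomly — makes fitting
deterministic and resolves component identity: components are re-sorted by
mean and matched to the seed ordering (T1: CSF < GM < WM; FLAIR:
CSF < WM < GM), so "the WM component" is defined by the atlas, not by fit
order. Sigmas are floored at 1e-3 of the data range; EM stops when the
log-likelihood improves by less than 1e-7 per sample or at 500 iterations.
The log-likelihood is non-decreasing by construction and the tests assert
it. A binned fast path (EM with responsibilities weighted by bin counts)
is provided and agrees with the voxel-sample path to a fraction of a
percent; the voxel path is the default for statistical fidelity.

Fitting happens twice per subject. With `lesions_excluded`, lesion-labeled
voxels are dropped before fitting: the WM parameters then describe
normal-appearing white matter. With `lesions_included`, lesion voxels stay
in the pool and are hard-assigned to the WM component (semi-supervised EM:
their responsibility is fixed, everything else is free). The reasoning is
anatomical: a white-matter lesion is white-matter tissue, so "lesions
included" must mean the WM class absorbs them. The design alternative — a
free fourth mixture component at the lesion locus — was implemented and
rejected: it absorbs the lesion voxels so cleanly that the included and
excluded WM sigmas agree to five decimals, which contradicts the defining
behavior of the included/excluded contrast (lesion exclusion narrows the
within-class distributions, and the WM sigma specifically). A plain k = 3
pooled fit fails differently: hyperintense lesions sit beyond GM on FLAIR,
so the GM component absorbs them and the WM component is untouched. The
semi-supervised assignment reproduces the intended effect on both
contrasts, with the excluded variant untouched.

The eight analyzed values per subject and variant are mu and sigma of GM
and WM on each contrast; CSF parameters are carried but flagged
unanalyzed, and the lesion metrics ride along in the output row.

## The statistical battery

All statistics consume a tidy per-subject table joined to a clinical table
on `subject_id`, complete cases per analysis.

* `groupAnova()` — one-way ANOVA of a parameter on the five groups
  (control, RRMS, SPMS, PPMS, PRMS); with eight parameters tested, the
  Bonferroni level is 0.05/8 = 0.00625.
* `posthocContrasts()` — all ten pairwise contrasts as unadjusted t tests
  on the pooled ANOVA error variance, with a star-bin coding
  (+ p<0.05, * p<1e-2, ** p<1e-3, *** p<1e-4, **** p<1e-5). No Tukey
  adjustment: the raw post-hoc thresholds are themselves the reported
  scale. A nonsignificant omnibus warns rather than gates.
* `rocAnalysis()` — AUC by the rank (Mann-Whitney) construction with
  mid-rank tie handling, which equals exhaustive concordant-pair counting
  (asserted against brute force in the tests). The operating point
  maximizes Youden's J, ties broken toward higher specificity; "auto"
  direction orients AUC at or above one half.
* `zscoreRegression()` — the biomarker is Z-scored over included subjects
  and regressed on PDDS by OLS, so slopes are comparable across
  biomarkers. PDDS is ordinal but treated as numeric deliberately,
  matching linear modeling practice for this scale; interpret slopes
  accordingly.
* `pcaComposite()` — first principal component of a standardized panel
  (neuroperformance, quality-of-life), sign-fixed so the largest loading
  is positive.
* `lassoDisabilityModel()` — L1-penalized regression of PDDS on the
  14-biomarker panel (8 GMM + 2 lesion + 4 atrophy covariates), trained on
  90 percent of complete cases with features Z-scored on the training
  split only, penalty by 10-fold CV (minimum-MSE rule; the 1-SE rule is
  exposed), evaluated on the held-out 10 percent as squared correlation.
  Split and folds are seed-reproducible.

## The synthetic generator

No patient data ship with the package; everything is exercised on
phantoms. Geometry is three concentric ellipsoids (CSF core, WM interior,
GM shell) sized to roughly 10/45/45 percent of brain — the method is
intensity-statistical, so class proportions matter and anatomy does not.
Classes draw bivariate Gaussian intensities at the normative loci with
SD 50 (intensity units) per contrast; lesions are spheres carved from WM
with FLAIR elevated to the atlas lesion locus and T1 depressed to the
GM/WM midpoint; diffuse NAWM pathology is an additive Gaussian field on WM
FLAIR (SD 0 in controls); scanner effects are exactly affine in the
intensity plane, so registration recovery is well-posed, with an optional
gamma nonlinearity to stress the QC gate. Everything is seeded and
byte-reproducible.

The cohort generator drives all disease expression from one latent
severity per subject: 0 in controls, mean 1 (SD 0.3) in RRMS, mean 2
(SD 0.4) shared by the three progressive subtypes — encoding the finding
that progressive subtypes are indistinguishable on these measures. Per
unit severity: T1 WM mean -30, T1 GM mean +15, FLAIR WM mean -15, FLAIR GM
mean -20 (units), all class SDs x(1 + 0.08), NAWM field SD +30, lesion
count Poisson(8). Between-subject variability independent of disease —
class-mean jitter SD 25 units and multiplicative sigma jitter SD 0.10 —
is essential realism: without it every parameter separates groups almost
perfectly and the characteristic ordering of discriminative value (FLAIR
WM sigma on top, driven by the WM-specific field) cannot emerge. PDDS is
1.5 x severity plus noise, rounded and clamped to 0-8; neuroperformance
(3 measures) and quality-of-life (12 domains) load on the same severity
with their own noise; atrophy covariates decline linearly in severity.
Scanner effects are drawn per subject (axis scalings 0.85-1.2, offsets
+/-40).

What phantoms do not emulate: partial-volume mixing at tissue boundaries,
spatially structured noise, real lesion morphology and periplaque
gradients, nonlinear intensity transfer, and site batch structure. Passing
tests therefore demonstrate correctness of the algorithms under the stated
model, not clinical performance.

## Problem sizes and numerical choices

Defaults used by the test-suite and the acceptance script: phantoms 48^3
voxels (about 42k brain voxels), cohort subjects 36^3, cohort of 160
(50/50/20/20/20 across the five groups), atlases from 5-10 controls,
parameter-recovery over 50 phantom replicates, null calibrations at 2000
simulations, LASSO behavior over 20 seeds. These sizes make the full suite
run in minutes on one core while leaving every estimate's Monte-Carlo
error well inside the asserted tolerances.

Degenerate inputs are handled explicitly: empty or tiny masks and
single-bin histograms are errors; empty tissue classes and non-convergence
are warnings carrying partial results; a mixture component collapsing
below weight 1e-4 is an error naming the likely cause; heavily overlapping
fitted components trigger a merged-components warning except where overlap
is by construction (hard-assigned lesion voxels). Assignment ties in
segmentation break toward the lower class code; EM component identity is
by seed ordering; all floating-point tolerances quoted above are the
implementation's actual constants.

## Limitations

The affine intensity map corrects global scanner effects only; genuinely
nonlinear intensity distortions leave residual alignment error, which is
exactly what the QC gate screens. Lesion labeling is intensity-based and
conservative by design, so mild lesions adjacent to the WM distribution
remain in the normal-appearing pool and partial-volume voxels may be
over-called as lesion; the lesion metrics should be read as conservative
burden summaries, not as a lesion-segmentation tool. The statistical
battery treats subjects as independent and PDDS as numeric; longitudinal
designs, covariate adjustment and site effects are out of scope.
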