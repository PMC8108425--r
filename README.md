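# histnorm

Quantitative signal from routine clinical brain MRI. `histnorm`
standardizes T1-weighted and FLAIR intensities by registering each
subject's bivariate intensity histogram to a normative reference, segments
CSF / gray matter / white matter / white-matter lesions in the
standardized intensity plane, extracts Gaussian-mixture signal parameters
for normal-appearing tissue, and provides the statistical battery that
relates those parameters to disability in multiple sclerosis cohorts.

## Who this is for

Imaging scientists who have conventional clinical acquisitions —
co-registered, brain-extracted, bias-corrected 3D T1w + FLAIR pairs in
arbitrary scanner units — and want scanner-independent, per-subject tissue
intensity biomarkers without quantitative relaxometry sequences. The
package consumes preprocessed NIfTI volumes; it does not do spatial
registration, brain extraction or bias correction.

## The method in brief

Each subject's in-brain voxels form a bivariate histogram over paired
intensities $x = (I_{T1w}, I_{FLAIR})$, in which tissue classes appear as
modes. A 6-parameter affine map of the intensity plane,

$$x' = A x + b, \qquad \det A > 0,$$

is fitted by minimizing the sum of squared differences between the
normalized, Gaussian-smoothed, square-root-transformed subject histogram
(pushed through the map with a $1/\det A$ Jacobian correction) and a
normative reference histogram averaged over a control cohort. The
functional value at the optimum is the subject's alignment error; subjects
above a fixed criterion are excluded (QC). The optimal map applied
voxelwise yields standardized images.

Voxels are then classified by a k-means-like iteration in the intensity
plane (lesion centroid frozen at the atlas prior, ambiguous hyperintense
voxels conservatively labeled lesion), and univariate Gaussian mixtures
fitted to each contrast yield the eight analyzed parameters
$\mu, \sigma$ for GM and WM on T1w and FLAIR — computed twice, with
lesions included in the WM class and with lesions excluded (the NAWM
variant). Lesion burden is summarized as volume and as the mean lesion
score $\bar u_{lv} = \frac{1}{n_L}\sum_{v \in L} u_l(v)$, the average
FLAIR elevation above the WM centroid in units of the WM-to-lesion
centroid gap.

The statistics module implements one-way group ANOVA at the Bonferroni
level $0.05/8$, pairwise post-hoc contrasts with star-bin coding,
rank-based ROC with Youden operating points, Z-scored linear regressions
of each biomarker on PDDS, first-principal-component composites of
neuroperformance and quality-of-life panels, and an L1-penalized (LASSO)
disability model with 90/10 hold-out validation.

A fully seeded synthetic module generates phantoms (nested-ellipsoid
geometry, per-class bivariate Gaussian intensities, spherical lesions,
diffuse NAWM FLAIR heterogeneity, affine scanner effects) and five-group
cohorts with a latent-severity disability model, so the entire pipeline is
testable end to end with known ground truth.

## Worked example

```r
library(histnorm)

# 1. normative atlas from control phantoms (use loadVolumePair() for real data)
controls <- lapply(1:5, function(i) generatePhantom(phantomSpec(seed = i))$pair)
atlas <- buildAtlas(controls)
atlas
#> ReferenceAtlas from 5 controls, 256 x 256 bins
#>   class centroids (t1, flair):
#>     CSF    (  200.69,   199.01)
#>     GM     (  602.07,  1101.85)
#>     WM     ( 1003.46,   703.83)
#>     LESION (  802.77,  1698.89)

# 2. an MS-like subject on a different scanner (affine intensity distortion)
ms <- generatePhantom(phantomSpec(
  seed = 42, lesionCount = 12, nawmFieldSD = 35,
  classMeans = list(t1 = c(CSF = 200, GM = 615, WM = 970),
                    flair = c(CSF = 200, WM = 685, GM = 1080)),
  scannerEffect = intensityAffine(diag(c(1.15, 0.9)), c(25, -15))))

res <- processSubject(ms$pair, atlas)
res$alignment
#> AlignmentResult: error = 0.0205916, converged after 1434 evaluations, QC pass
#> IntensityAffine x' = A x + b
#>   A = [  0.9255  -0.0542;   0.0096   1.1230], det = 1.0399
#>   b = (-25.453, 15.854)

res$row[, c("variant", "t1_wm_mu", "flair_wm_sigma",
            "lesion_volume", "lesion_intensity")]
#>            variant t1_wm_mu flair_wm_sigma lesion_volume lesion_intensity
#> 1 lesions_excluded 998.4316       61.86135         0.357         1.013092
#> 2 lesions_included 993.3143      186.03478         0.357         1.013092
```

Reading the output: the recovered transform is close to the inverse of the
simulated scanner effect (scalings 1/1.15 and 1/0.9, offsets undone), so
standardization has put the subject on the atlas scale. The NAWM variant's
FLAIR WM sigma (61.9) sits well above the control value of 50 — the
diffuse heterogeneity the phantom planted — while including the lesion
voxels in the WM class widens it much further (186.0). Lesion burden is
0.357 mL with a mean lesion score of about 1.0, i.e. lesions at full
lesion-locus intensity. On a cohort, `runStats()` turns a stack of such
rows plus a clinical table into ANOVA/contrast, ROC, regression, PCA and
LASSO summaries.

A thin command-line wrapper with `build-atlas`, `process-subject`,
`run-stats`, `make-phantom` and `make-cohort` subcommands is installed at
`inst/cli/histnorm.R`.

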