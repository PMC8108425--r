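#' @import methods
#' @importFrom stats optim aov lm anova pt pf dnorm quantile sd var median mad
#'   prcomp predict coef rnorm runif rpois complete.cases setNames density
#'   cor reformulate
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib histnorm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Tissue class codes used throughout: 0 = background (off-mask),
## 1 = CSF, 2 = GM, 3 = WM, 4 = LESION.
.TISSUES <- c("CSF", "GM", "WM", "LESION")
.CODE <- c(CSF = 1L, GM = 2L, WM = 3L, LESION = 4L)

#' Binning specification for bivariate intensity histograms
#'
#' Defines the number of bins and the intensity range on each axis of the
#' (T1w, FLAIR) intensity plane. Ranges are set once when the reference atlas
#' is built (mode \code{"robust_percentile"}) or supplied directly (mode
#' \code{"fixed"}) and are then frozen: every subject is histogrammed on the
#' atlas binning so that histogram registration is meaningful.
#'
#' @slot nBinsT1 number of bins on the T1w axis (>= 32)
#' @slot nBinsFlair number of bins on the FLAIR axis (>= 32)
#' @slot rangeT1 numeric length-2, (lo, hi) in scanner units
#' @slot rangeFlair numeric length-2, (lo, hi) in scanner units
#' @slot rangeMode \code{"fixed"} or \code{"robust_percentile"}
#' @exportClass BinningSpec
setClass("BinningSpec",
  representation(nBinsT1 = "integer", nBinsFlair = "integer",
                 rangeT1 = "numeric", rangeFlair = "numeric",
                 rangeMode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nBinsT1 < 32L || object@nBinsFlair < 32L)
      msg <- c(msg, "at least 32 bins required on each axis")
    if (length(object@rangeT1) != 2L || diff(object@rangeT1) <= 0)
      msg <- c(msg, "rangeT1 must be (lo, hi) with hi > lo")
    if (length(object@rangeFlair) != 2L || diff(object@rangeFlair) <= 0)
      msg <- c(msg, "rangeFlair must be (lo, hi) with hi > lo")
    if (!object@rangeMode %in% c("fixed", "robust_percentile"))
      msg <- c(msg, "rangeMode must be 'fixed' or 'robust_percentile'")
    if (length(msg)) msg else TRUE
  })

#' Co-registered T1w + FLAIR volume pair with brain mask
#'
#' The raw material of the pipeline: two spatially co-registered,
#' brain-extracted, bias-field-corrected 3D volumes plus a binary brain mask,
#' all with identical array dimensions. The pipeline validates shape only; it
#' never resamples (spatial preprocessing is upstream of this tool).
#'
#' In-mask voxels are linearized in R's native column-major array order;
#' this fixed, documented order is what maps labels and intensities back to
#' voxel locations.
#'
#' @slot t1w 3D numeric array, arbitrary scanner units
#' @slot flair 3D numeric array, same dimensions
#' @slot brainMask 3D array, nonzero = brain
#' @slot voxelSize mm per axis, length 3
#' @slot subjectId opaque identifier
#' @slot standardized TRUE once intensities have been mapped to atlas space
#' @exportClass VolumePair
setClass("VolumePair",
  representation(t1w = "array", flair = "array", brainMask = "array",
                 voxelSize = "numeric", subjectId = "character",
                 standardized = "logical"),
  prototype(voxelSize = c(1, 1, 1), subjectId = "subject",
            standardized = FALSE),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@t1w), dim(object@flair)) ||
        !identical(dim(object@t1w), dim(object@brainMask)))
      msg <- c(msg, "t1w, flair and brainMask must have identical dimensions")
    if (length(dim(object@t1w)) != 3L)
      msg <- c(msg, "volumes must be 3D")
    if (sum(object@brainMask != 0) < 1L)
      msg <- c(msg, "brain mask is empty")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive numbers (mm)")
    if (length(msg)) msg else TRUE
  })

#' Paired in-mask voxel intensities
#'
#' One (T1w, FLAIR) intensity pair per in-mask voxel, in the fixed
#' column-major linearization of the mask, with non-finite voxels dropped and
#' counted.
#'
#' @slot t1 numeric vector of T1w intensities
#' @slot flair numeric vector of FLAIR intensities, same length and order
#' @slot voxelIdx integer linear indices into the 3D array
#' @slot nExcluded number of in-mask voxels dropped for non-finite intensity
#' @exportClass PairedIntensities
setClass("PairedIntensities",
  representation(t1 = "numeric", flair = "numeric", voxelIdx = "integer",
                 nExcluded = "integer"),
  validity = function(object) {
    if (length(object@t1) != length(object@flair) ||
        length(object@t1) != length(object@voxelIdx))
      return("t1, flair and voxelIdx must have equal length")
    TRUE
  })

#' Bivariate (T1w x FLAIR) intensity histogram
#'
#' 2D count array over the intensity plane; the object that is affinely
#' registered to the normative reference. Histograms are stored raw (counts)
#' and normalized on demand, so count-conservation can always be checked.
#'
#' @slot counts nBinsT1 x nBinsFlair non-negative matrix (T1w on rows)
#' @slot edgesT1 strictly increasing bin edges, length nBinsT1 + 1
#' @slot edgesFlair strictly increasing bin edges, length nBinsFlair + 1
#' @slot nTotal number of contributing voxels
#' @slot normalized TRUE if counts sum to 1
#' @exportClass BivariateHistogram
setClass("BivariateHistogram",
  representation(counts = "matrix", edgesT1 = "numeric",
                 edgesFlair = "numeric", nTotal = "numeric",
                 normalized = "logical"),
  validity = function(object) {
    msg <- character()
    if (any(object@counts < 0)) msg <- c(msg, "negative counts")
    if (length(object@edgesT1) != nrow(object@counts) + 1L)
      msg <- c(msg, "edgesT1 length must be nrow(counts)+1")
    if (length(object@edgesFlair) != ncol(object@counts) + 1L)
      msg <- c(msg, "edgesFlair length must be ncol(counts)+1")
    if (any(diff(object@edgesT1) <= 0) || any(diff(object@edgesFlair) <= 0))
      msg <- c(msg, "bin edges must be strictly increasing")
    s <- sum(object@counts)
    if (object@normalized) {
      if (abs(s - 1) > 1e-9) msg <- c(msg, "normalized counts must sum to 1")
    } else if (abs(s - object@nTotal) > 1e-6 * max(1, object@nTotal)) {
      msg <- c(msg, "raw counts must sum to nTotal")
    }
    if (length(msg)) msg else TRUE
  })

#' Normative reference atlas
#'
#' The normalized mean bivariate histogram of a control cohort, together with
#' the tissue-class centroid loci found on it and the frozen binning every
#' subject is histogrammed on. Centroids obey the control-ordering
#' constraints: on T1w, CSF < GM < WM; on FLAIR, CSF < WM < GM, with the
#' LESION locus hyperintense to WM on FLAIR.
#'
#' @slot reference normalized \linkS4class{BivariateHistogram}
#' @slot classCentroids 4 x 2 matrix, rows CSF/GM/WM/LESION, cols t1/flair
#' @slot nControls number of control subjects averaged
#' @slot binning the frozen \linkS4class{BinningSpec}
#' @exportClass ReferenceAtlas
setClass("ReferenceAtlas",
  representation(reference = "BivariateHistogram",
                 classCentroids = "matrix", nControls = "integer",
                 binning = "BinningSpec"),
  validity = function(object) {
    msg <- character()
    cc <- object@classCentroids
    if (!identical(rownames(cc), .TISSUES) || ncol(cc) != 2L)
      msg <- c(msg, "classCentroids must be a 4x2 matrix CSF/GM/WM/LESION")
    else {
      if (!(cc["CSF", 1] < cc["GM", 1] && cc["GM", 1] < cc["WM", 1]))
        msg <- c(msg, "T1 centroid ordering CSF < GM < WM violated")
      if (!(cc["CSF", 2] < cc["WM", 2] && cc["WM", 2] < cc["GM", 2]))
        msg <- c(msg, "FLAIR centroid ordering CSF < WM < GM violated")
      if (!(cc["LESION", 2] > cc["WM", 2]))
        msg <- c(msg, "LESION FLAIR centroid must exceed WM")
    }
    if (!object@reference@normalized)
      msg <- c(msg, "reference histogram must be normalized")
    if (length(msg)) msg else TRUE
  })

#' Affine map of the 2D intensity plane
#'
#' Maps a subject-space intensity pair x = (t1, flair) into reference space
#' via x' = A x + b. Orientation-preserving: det(A) > 0.
#'
#' @slot linear 2x2 matrix A
#' @slot offset length-2 vector b, scanner/reference intensity units
#' @exportClass IntensityAffine
setClass("IntensityAffine",
  representation(linear = "matrix", offset = "numeric"),
  prototype(linear = diag(2), offset = c(0, 0)),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@linear), c(2L, 2L)))
      msg <- c(msg, "linear must be 2x2")
    else if (det(object@linear) <= 0)
      msg <- c(msg, "det(A) must be > 0 (orientation-preserving)")
    if (length(object@offset) != 2L) msg <- c(msg, "offset must be length 2")
    if (length(msg)) msg else TRUE
  })

#' Result of registering a subject histogram to the reference
#'
#' @slot transform the recovered \linkS4class{IntensityAffine}
#' @slot error alignment error: the dissimilarity functional at the optimum
#' @slot converged did the best optimizer run converge
#' @slot nIterations function evaluations used by the best run
#' @slot qcPass error <= configured QC threshold
#' @slot qcThreshold the threshold qcPass was evaluated against
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(transform = "IntensityAffine", error = "numeric",
                 converged = "logical", nIterations = "integer",
                 qcPass = "logical", qcThreshold = "numeric"),
  validity = function(object) {
    if (object@error < 0) return("alignment error must be >= 0")
    TRUE
  })

#' Voxelwise tissue label map
#'
#' Integer volume with codes 0 background, 1 CSF, 2 GM, 3 WM, 4 LESION.
#' Labels partition the brain mask. \code{excludeLesions()} marks lesion
#' voxels excluded (tracked in \code{excluded}) without relabeling them, so
#' WM voxel sets are identical before and after exclusion.
#'
#' @slot labels 3D integer array of class codes
#' @slot classCounts named count per tissue class
#' @slot centroids converged 4x2 class centroid matrix (t1, flair)
#' @slot excluded integer linear indices of voxels excluded from analysis
#' @slot converged k-means iteration converged
#' @exportClass TissueLabelMap
setClass("TissueLabelMap",
  representation(labels = "array", classCounts = "numeric",
                 centroids = "matrix", excluded = "integer",
                 converged = "logical"),
  prototype(excluded = integer(), converged = TRUE),
  validity = function(object) {
    if (!identical(names(object@classCounts), .TISSUES))
      return("classCounts must be named CSF/GM/WM/LESION")
    if (sum(object@classCounts) != sum(object@labels != 0L))
      return("classCounts must sum to the number of labeled voxels")
    TRUE
  })

#' White-matter lesion burden metrics
#'
#' Lesion volume in mL (voxel count times voxel volume) and the mean lesion
#' intensity score u_lv = (1/nL) * sum over lesion voxels of u_l, where the
#' per-voxel lesion score u_l is the voxel's FLAIR elevation above the WM
#' centroid in units of the WM-to-LESION centroid gap, clipped at 0. The
#' intensity score is undefined (NA) when no lesion voxels exist.
#'
#' @slot lesionVolumeML lesion volume, mL
#' @slot lesionIntensity mean lesion score u_lv (dimensionless), NA if none
#' @slot nLesionVoxels lesion voxel count
#' @exportClass LesionMetrics
setClass("LesionMetrics",
  representation(lesionVolumeML = "numeric", lesionIntensity = "numeric",
                 nLesionVoxels = "integer"),
  validity = function(object) {
    if (object@lesionVolumeML < 0) return("lesion volume must be >= 0")
    TRUE
  })

#' Per-subject GMM signal parameters
#'
#' The eight analyzed parameters — mean (mu) and standard deviation (sigma)
#' of the GM and WM Gaussian components on each contrast — for one variant
#' (lesions included or excluded), plus the unanalyzed CSF components and
#' the subject's lesion metrics. Component identity is resolved by the
#' atlas mu-ordering (T1: CSF < GM < WM; FLAIR: CSF < WM < GM), never by
#' fit order.
#'
#' @slot subjectId subject identifier
#' @slot variant "lesions_included" or "lesions_excluded"
#' @slot parameters named numeric of the 8 analyzed values
#' @slot csf named numeric of the unanalyzed CSF mu/sigma per contrast
#' @slot lesion \linkS4class{LesionMetrics}
#' @slot mixtures list of full fitted component tables per contrast
#' @exportClass SubjectParameters
setClass("SubjectParameters",
  representation(subjectId = "character", variant = "character",
                 parameters = "numeric", csf = "numeric",
                 lesion = "LesionMetrics", mixtures = "list"),
  validity = function(object) {
    need <- c("t1_wm_mu", "t1_gm_mu", "t1_wm_sigma", "t1_gm_sigma",
              "flair_wm_mu", "flair_gm_mu", "flair_wm_sigma", "flair_gm_sigma")
    if (!all(need %in% names(object@parameters)))
      return("parameters must contain the 8 analyzed values")
    sig <- object@parameters[grep("sigma", names(object@parameters))]
    if (any(sig <= 0)) return("all sigmas must be positive")
    if (!object@variant %in% c("lesions_included", "lesions_excluded"))
      return("variant must be lesions_included or lesions_excluded")
    TRUE
  })
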