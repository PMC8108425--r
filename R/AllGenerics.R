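#' @rdname BivariateHistogram-class
#' @param object a package object
#' @export
setGeneric("histCounts", function(object) standardGeneric("histCounts"))
#' @rdname BivariateHistogram-class
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))
#' @rdname BivariateHistogram-class
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname ReferenceAtlas-class
#' @export
setGeneric("classCentroids", function(object) standardGeneric("classCentroids"))
#' @rdname ReferenceAtlas-class
#' @export
setGeneric("referenceHistogram",
           function(object) standardGeneric("referenceHistogram"))
#' @rdname ReferenceAtlas-class
#' @export
setGeneric("binning", function(object) standardGeneric("binning"))
#' @rdname TissueLabelMap-class
#' @export
setGeneric("tissueLabels", function(object) standardGeneric("tissueLabels"))
#' @rdname TissueLabelMap-class
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))
#' @rdname TissueLabelMap-class
#' @export
setGeneric("excludedVoxels", function(object) standardGeneric("excludedVoxels"))
#' @rdname AlignmentResult-class
#' @export
setGeneric("alignTransform", function(object) standardGeneric("alignTransform"))
#' @rdname AlignmentResult-class
#' @export
setGeneric("alignError", function(object) standardGeneric("alignError"))
#' @rdname SubjectParameters-class
#' @export
setGeneric("analyzedParameters",
           function(object) standardGeneric("analyzedParameters"))
#' @rdname SubjectParameters-class
#' @export
setGeneric("lesionBurden", function(object) standardGeneric("lesionBurden"))

#' @rdname BivariateHistogram-class
setMethod("histCounts", "BivariateHistogram", function(object) object@counts)
#' @rdname BivariateHistogram-class
setMethod("binEdges", "BivariateHistogram",
          function(object) list(t1 = object@edgesT1, flair = object@edgesFlair))
#' @rdname BivariateHistogram-class
setMethod("nVoxels", "BivariateHistogram", function(object) object@nTotal)
#' @rdname VolumePair-class
setMethod("nVoxels", "VolumePair",
          function(object) sum(object@brainMask != 0))
#' @rdname PairedIntensities-class
#' @param object a \code{PairedIntensities}
setMethod("nVoxels", "PairedIntensities", function(object) length(object@t1))

#' @rdname ReferenceAtlas-class
setMethod("classCentroids", "ReferenceAtlas",
          function(object) object@classCentroids)
#' @rdname TissueLabelMap-class
setMethod("classCentroids", "TissueLabelMap", function(object) object@centroids)
#' @rdname ReferenceAtlas-class
setMethod("referenceHistogram", "ReferenceAtlas",
          function(object) object@reference)
#' @rdname ReferenceAtlas-class
setMethod("binning", "ReferenceAtlas", function(object) object@binning)

#' @rdname TissueLabelMap-class
setMethod("tissueLabels", "TissueLabelMap", function(object) object@labels)
#' @rdname TissueLabelMap-class
setMethod("classCounts", "TissueLabelMap", function(object) object@classCounts)
#' @rdname TissueLabelMap-class
setMethod("excludedVoxels", "TissueLabelMap", function(object) object@excluded)

#' @rdname AlignmentResult-class
setMethod("alignTransform", "AlignmentResult", function(object) object@transform)
#' @rdname AlignmentResult-class
setMethod("alignError", "AlignmentResult", function(object) object@error)

#' @rdname SubjectParameters-class
setMethod("analyzedParameters", "SubjectParameters",
          function(object) object@parameters)
#' @rdname SubjectParameters-class
setMethod("lesionBurden", "SubjectParameters", function(object) object@lesion)

setMethod("show", "VolumePair", function(object) {
  d <- dim(object@t1w)
  cat(sprintf("VolumePair '%s': %dx%dx%d voxels (%.2gx%.2gx%.2g mm), %d in mask%s\n",
              object@subjectId, d[1], d[2], d[3], object@voxelSize[1],
              object@voxelSize[2], object@voxelSize[3],
              sum(object@brainMask != 0),
              if (object@standardized) ", standardized" else ""))
})

setMethod("show", "BivariateHistogram", function(object) {
  cat(sprintf("BivariateHistogram: %d x %d bins, %s, n = %g voxels\n",
              nrow(object@counts), ncol(object@counts),
              if (object@normalized) "normalized" else "raw counts",
              object@nTotal))
  cat(sprintf("  T1 range [%.4g, %.4g], FLAIR range [%.4g, %.4g]\n",
              min(object@edgesT1), max(object@edgesT1),
              min(object@edgesFlair), max(object@edgesFlair)))
})

setMethod("show", "ReferenceAtlas", function(object) {
  cat(sprintf("ReferenceAtlas from %d controls, %d x %d bins\n",
              object@nControls, object@binning@nBinsT1,
              object@binning@nBinsFlair))
  cat("  class centroids (t1, flair):\n")
  for (cl in .TISSUES)
    cat(sprintf("    %-6s (%8.2f, %8.2f)\n", cl,
                object@classCentroids[cl, 1], object@classCentroids[cl, 2]))
})

setMethod("show", "IntensityAffine", function(object) {
  A <- object@linear; b <- object@offset
  cat("IntensityAffine x' = A x + b\n")
  cat(sprintf("  A = [%8.4f %8.4f; %8.4f %8.4f], det = %.4f\n",
              A[1, 1], A[1, 2], A[2, 1], A[2, 2], det(A)))
  cat(sprintf("  b = (%.3f, %.3f)\n", b[1], b[2]))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: error = %.6g, %s after %d evaluations, QC %s\n",
              object@error,
              if (object@converged) "converged" else "NOT converged",
              object@nIterations,
              if (isTRUE(object@qcPass)) "pass" else "FAIL"))
  show(object@transform)
})

setMethod("show", "TissueLabelMap", function(object) {
  cat("TissueLabelMap voxel counts:",
      paste(sprintf("%s=%d", .TISSUES, object@classCounts), collapse = " "),
      "\n")
  if (length(object@excluded))
    cat(sprintf("  %d voxels excluded from analysis\n",
                length(object@excluded)))
})

setMethod("show", "SubjectParameters", function(object) {
  cat(sprintf("SubjectParameters '%s' (%s)\n", object@subjectId,
              object@variant))
  print(round(object@parameters, 3))
  lm0 <- object@lesion
  cat(sprintf("  lesions: %d voxels, %.3f mL, intensity u_lv = %s\n",
              lm0@nLesionVoxels, lm0@lesionVolumeML,
              ifelse(is.na(lm0@lesionIntensity), "NA",
                     sprintf("%.3f", lm0@lesionIntensity))))
})

#' Flatten subject parameters to a one-row data frame
#'
#' @param x a \linkS4class{SubjectParameters}
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return one-row data.frame: subject_id, variant, the 8 analyzed
#'   parameters, lesion metrics
#' @export
as.data.frame.SubjectParameters <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(subject_id = x@subjectId, variant = x@variant,
             as.list(x@parameters),
             lesion_volume = x@lesion@lesionVolumeML,
             lesion_intensity = x@lesion@lesionIntensity,
             n_lesion_voxels = x@lesion@nLesionVoxels,
             stringsAsFactors = FALSE)
}
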