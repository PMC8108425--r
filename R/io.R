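#' Construct a VolumePair from in-memory arrays
#'
#' @param t1w,flair,brainMask 3D arrays of identical dimension
#' @param voxelSize mm per axis (length 3)
#' @param subjectId identifier string
#' @param standardized whether intensities are already in atlas space
#' @return a \linkS4class{VolumePair}
#' @export
volumePair <- function(t1w, flair, brainMask, voxelSize = c(1, 1, 1),
                       subjectId = "subject", standardized = FALSE) {
  new("VolumePair", t1w = .as3d(t1w), flair = .as3d(flair),
      brainMask = .as3d(brainMask), voxelSize = as.numeric(voxelSize),
      subjectId = subjectId, standardized = standardized)
}

.as3d <- function(x) {
  x <- unclass(x)
  d <- dim(x)
  if (is.null(d)) stop("volume has no dimensions")
  d <- d[d > 1L | seq_along(d) <= 3L]   # drop trailing singleton dims
  if (length(dim(x)) > 3L) dim(x) <- dim(x)[1:3]
  if (length(dim(x)) != 3L) stop("volume must be 3D")
  array(as.numeric(x), dim = dim(x))
}

#' Load a co-registered T1w/FLAIR/mask triplet from NIfTI files
#'
#' Reads the three volumes, validates that they share dimensions (a mismatch
#' signals volumes that were not co-registered/resampled upstream) and that
#' the mask is usable, and records the voxel size from the T1w header.
#' Negative in-mask intensities (possible bias-correction artifacts) are
#' permitted but flagged with a warning; they are clipped later, at the
#' histogram stage, so that I/O stays lossless.
#'
#' @param t1Path,flairPath,maskPath paths to NIfTI (.nii/.nii.gz) volumes;
#'   any nonzero mask value is interpreted as brain
#' @param subjectId identifier; defaults to the T1w file stem
#' @param minMaskVoxels degenerate-input guard (default 1000)
#' @return a validated \linkS4class{VolumePair}
#' @export
loadVolumePair <- function(t1Path, flairPath, maskPath,
                           subjectId = NULL, minMaskVoxels = 1000L) {
  for (p in c(t1Path, flairPath, maskPath))
    if (!file.exists(p)) stop("cannot read file: ", p)
  t1 <- RNifti::readNifti(t1Path)
  fl <- RNifti::readNifti(flairPath)
  mk <- RNifti::readNifti(maskPath)
  if (!identical(dim(t1)[1:3], dim(fl)[1:3]) ||
      !identical(dim(t1)[1:3], dim(mk)[1:3]))
    stop("shape mismatch between volumes: inputs must be co-registered and ",
         "resampled to a common grid (t1 ", paste(dim(t1), collapse = "x"),
         ", flair ", paste(dim(fl), collapse = "x"), ", mask ",
         paste(dim(mk), collapse = "x"), ")")
  vs <- RNifti::pixdim(t1)[1:3]
  if (any(!is.finite(vs)) || any(vs <= 0)) vs <- c(1, 1, 1)
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(t1Path))
  pair <- volumePair(t1, fl, mk, voxelSize = vs, subjectId = subjectId)
  nm <- sum(pair@brainMask != 0)
  if (nm < minMaskVoxels)
    stop("brain mask has only ", nm, " voxels (< ", minMaskVoxels,
         "): empty or degenerate mask")
  inmask <- pair@brainMask != 0
  if (any(pair@t1w[inmask] < 0, na.rm = TRUE) ||
      any(pair@flair[inmask] < 0, na.rm = TRUE))
    warning("negative in-mask intensities present; they will be clipped at ",
            "the histogram stage")
  pair
}

#' Write a VolumePair to NIfTI files
#'
#' @param pair a \linkS4class{VolumePair}
#' @param t1Path,flairPath,maskPath output paths (.nii or .nii.gz); any that
#'   are NULL are skipped
#' @return invisibly, the paths written
#' @export
writeVolumePair <- function(pair, t1Path, flairPath, maskPath = NULL) {
  stopifnot(is(pair, "VolumePair"))
  pd <- pair@voxelSize
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path)
    path
  }
  out <- c(if (!is.null(t1Path)) wr(pair@t1w, t1Path),
           if (!is.null(flairPath)) wr(pair@flair, flairPath),
           if (!is.null(maskPath)) wr(pair@brainMask, maskPath))
  invisible(out)
}

#' Extract paired in-mask intensities
#'
#' Returns exactly the in-mask voxels, paired by spatial location, in the
#' fixed column-major linearization of the 3D array. Voxels with a
#' non-finite value on either contrast are excluded and counted; a pure
#' function of (volumes, mask) — off-mask voxels never influence the output.
#'
#' @param pair a \linkS4class{VolumePair}
#' @return a \linkS4class{PairedIntensities}
#' @export
extractPairedIntensities <- function(pair) {
  stopifnot(is(pair, "VolumePair"))
  idx <- which(pair@brainMask != 0)      # column-major linearization
  t1 <- pair@t1w[idx]
  fl <- pair@flair[idx]
  ok <- is.finite(t1) & is.finite(fl)
  nExcl <- sum(!ok)
  if (!any(ok)) stop("all in-mask voxels are non-finite")
  new("PairedIntensities", t1 = t1[ok], flair = fl[ok],
      voxelIdx = as.integer(idx[ok]), nExcluded = as.integer(nExcl))
}
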