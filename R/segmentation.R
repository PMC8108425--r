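#' Segmentation settings
#'
#' The conservative lesion rule relabels as LESION any voxel whose FLAIR
#' intensity exceeds the converged WM centroid by more than
#' \code{flairMarginFrac} of the WM-to-LESION FLAIR centroid gap AND whose
#' nearest/second-nearest centroid distance ratio exceeds
#' \code{ambiguityRatio} (an ambiguous, borderline voxel). Lowering either
#' margin is more conservative: more voxels are pushed out of the
#' normal-appearing tissue pool into the lesion class, and the lesion count
#' is monotone non-decreasing in that direction.
#'
#' @param flairMarginFrac FLAIR elevation required, as a fraction of the
#'   WM-to-LESION centroid gap (default 0.5)
#' @param ambiguityRatio distance-ratio threshold above which an assignment
#'   counts as ambiguous (default 0.8)
#' @param tol convergence tolerance on centroid motion, in bin widths
#' @param maxIter iteration cap for the k-means-like loop
#' @param minComponentSize if > 0, drop LESION components (26-connectivity)
#'   smaller than this many voxels back to WM; 0 disables the spatial filter
#'   (classification is intensity-only by default)
#' @return a list of settings
#' @export
segmentationOptions <- function(flairMarginFrac = 0.5, ambiguityRatio = 0.8,
                                tol = 1e-3, maxIter = 100L,
                                minComponentSize = 0L) {
  list(flairMarginFrac = flairMarginFrac, ambiguityRatio = ambiguityRatio,
       tol = tol, maxIter = maxIter,
       minComponentSize = as.integer(minComponentSize))
}

#' Classify voxels into CSF / GM / WM / LESION
#'
#' A k-means-like iteration in the standardized bivariate intensity plane:
#' voxels are assigned to the nearest class centroid under Euclidean
#' distance in bin-width-scaled coordinates (each axis divided by its bin
#' width, so T1 and FLAIR contribute comparably); the CSF, GM and WM
#' centroids are then recomputed from the assignments while the LESION
#' centroid stays frozen at the atlas prior (lesions are rare or absent in
#' controls, and a free lesion centroid collapses onto WM). After
#' convergence the conservative lesion rule (see
#' \code{\link{segmentationOptions}}) relabels ambiguous hyperintense voxels
#' as LESION. Assignment ties break toward the lower class code. Fully
#' deterministic: no randomness anywhere.
#'
#' @param pair a standardized \linkS4class{VolumePair} (output of
#'   \code{\link{applyIntensityTransform}})
#' @param atlas the \linkS4class{ReferenceAtlas}
#' @param opts settings from \code{\link{segmentationOptions}}
#' @return a \linkS4class{TissueLabelMap}
#' @export
classifyTissues <- function(pair, atlas, opts = segmentationOptions()) {
  stopifnot(is(pair, "VolumePair"), is(atlas, "ReferenceAtlas"))
  if (!pair@standardized)
    warning("pair is not flagged standardized; classifying raw intensities ",
            "against atlas centroids is usually a mistake")
  vals <- extractPairedIntensities(pair)
  e <- .edges(atlas@binning)
  w1 <- diff(e$t1[1:2]); w2 <- diff(e$flair[1:2])
  x1 <- vals@t1 / w1
  x2 <- vals@flair / w2
  C <- atlas@classCentroids
  Cs <- cbind(C[, 1] / w1, C[, 2] / w2)      # scaled centroids, rows CSF..LESION
  n <- length(x1)
  D <- matrix(0, n, 4L)
  converged <- FALSE
  for (iter in seq_len(opts$maxIter)) {
    for (k in 1:4) D[, k] <- (x1 - Cs[k, 1])^2 + (x2 - Cs[k, 2])^2
    lab <- max.col(-D, ties.method = "first")  # ties -> lower class code
    Cnew <- Cs
    for (k in 1:3) {                           # LESION centroid frozen
      sel <- lab == k
      if (any(sel)) Cnew[k, ] <- c(mean(x1[sel]), mean(x2[sel]))
    }
    motion <- max(abs(Cnew - Cs))
    Cs <- Cnew
    if (motion <= opts$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("tissue classification did not converge in ", opts$maxIter,
            " iterations")
  for (k in 1:4) D[, k] <- (x1 - Cs[k, 1])^2 + (x2 - Cs[k, 2])^2
  lab <- max.col(-D, ties.method = "first")

  ## conservative lesion rule on ambiguous FLAIR-hyperintense voxels
  flairThresh <- Cs["WM", 2] +
    opts$flairMarginFrac * (Cs["LESION", 2] - Cs["WM", 2])
  Ds <- sqrt(D)
  d1 <- Ds[cbind(seq_len(n), lab)]
  Ds[cbind(seq_len(n), lab)] <- Inf
  d2 <- pmin(Ds[, 1], Ds[, 2], Ds[, 3], Ds[, 4])
  ambiguous <- d1 / pmax(d2, .Machine$double.eps) > opts$ambiguityRatio
  lab[lab != 4L & ambiguous & x2 > flairThresh] <- 4L

  labels <- array(0L, dim = dim(pair@t1w))
  labels[vals@voxelIdx] <- lab
  if (opts$minComponentSize > 0L)
    labels <- .filterSmallLesions(labels, opts$minComponentSize)
  cnt <- vapply(1:4, function(k) sum(labels == k), numeric(1))
  names(cnt) <- .TISSUES
  for (cl in .TISSUES[cnt == 0]) warning("empty tissue class: ", cl)
  centroids <- cbind(t1 = Cs[, 1] * w1, flair = Cs[, 2] * w2)
  rownames(centroids) <- .TISSUES
  new("TissueLabelMap", labels = labels, classCounts = cnt,
      centroids = centroids, excluded = integer(), converged = converged)
}

## drop LESION connected components (26-neighborhood) below minSize, back to WM
.filterSmallLesions <- function(labels, minSize) {
  d <- dim(labels)
  les <- which(labels == 4L)
  if (!length(les)) return(labels)
  coord <- arrayInd(les, d)
  key <- function(m) (m[, 3] - 1L) * d[1] * d[2] + (m[, 2] - 1L) * d[1] + m[, 1]
  inLesion <- new.env(hash = TRUE)
  for (i in seq_along(les)) assign(as.character(les[i]), i, envir = inLesion)
  seen <- logical(length(les))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_along(les)) {
    if (seen[i]) next
    comp <- i; queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2, coord[cur, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      for (k in key(nb[ok, , drop = FALSE])) {
        j <- mget(as.character(k), envir = inLesion,
                  ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) {
          seen[j] <- TRUE; queue <- c(queue, j); comp <- c(comp, j)
        }
      }
    }
    if (length(comp) < minSize) labels[les[comp]] <- 3L
  }
  labels
}

#' Mark lesion voxels as excluded from analysis
#'
#' Returns a copy of the label map in which LESION voxels are marked
#' excluded — not reassigned to WM — so the WM voxel set is identical before
#' and after exclusion and the exclusion is reversible.
#'
#' @param labelMap a \linkS4class{TissueLabelMap}
#' @return the label map with \code{excludedVoxels()} populated
#' @export
excludeLesions <- function(labelMap) {
  stopifnot(is(labelMap, "TissueLabelMap"))
  initialize(labelMap,
             excluded = as.integer(which(labelMap@labels == .CODE[["LESION"]])))
}

#' Lesion volume and intensity metrics
#'
#' Lesion volume is the lesion voxel count times the voxel volume (mL).
#' The per-voxel lesion score u_l is the voxel's standardized FLAIR
#' elevation above the converged WM centroid, in units of the WM-to-LESION
#' centroid gap, clipped at zero; lesion intensity u_lv is the mean score
#' over lesion voxels (NA when there are none).
#'
#' @param labelMap a \linkS4class{TissueLabelMap}
#' @param pair the standardized \linkS4class{VolumePair} it was computed from
#' @param atlas the \linkS4class{ReferenceAtlas} (source of the frozen
#'   LESION centroid)
#' @return a \linkS4class{LesionMetrics}
#' @export
lesionMetrics <- function(labelMap, pair, atlas) {
  stopifnot(is(labelMap, "TissueLabelMap"), is(pair, "VolumePair"))
  idx <- which(labelMap@labels == .CODE[["LESION"]])
  nL <- length(idx)
  volML <- nL * prod(pair@voxelSize) / 1000
  if (nL == 0L)
    return(new("LesionMetrics", lesionVolumeML = 0,
               lesionIntensity = NA_real_, nLesionVoxels = 0L))
  wmF <- labelMap@centroids["WM", "flair"]
  lesF <- labelMap@centroids["LESION", "flair"]
  u <- pmax(0, (pair@flair[idx] - wmF) / (lesF - wmF))
  new("LesionMetrics", lesionVolumeML = volML,
      lesionIntensity = mean(u), nLesionVoxels = as.integer(nL))
}

#' Write a tissue label map as NIfTI
#'
#' Integer codes: 0 background, 1 CSF, 2 GM, 3 WM, 4 LESION.
#'
#' @param labelMap a \linkS4class{TissueLabelMap}
#' @param path output path (.nii/.nii.gz)
#' @param voxelSize mm per axis for the header
#' @return the path, invisibly
#' @export
writeLabelMap <- function(labelMap, path, voxelSize = c(1, 1, 1)) {
  img <- RNifti::asNifti(labelMap@labels)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}
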