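#' Create a binning specification
#'
#' @param nBinsT1,nBinsFlair bin counts (>= 32); default 256
#' @param rangeT1,rangeFlair (lo, hi) intensity ranges in scanner units
#' @param rangeMode "fixed" if ranges were supplied directly,
#'   "robust_percentile" if derived from a control pool (see
#'   \code{\link{robustBinning}})
#' @return a \linkS4class{BinningSpec}
#' @export
binningSpec <- function(nBinsT1 = 256L, nBinsFlair = 256L,
                        rangeT1, rangeFlair, rangeMode = "fixed") {
  new("BinningSpec", nBinsT1 = as.integer(nBinsT1),
      nBinsFlair = as.integer(nBinsFlair),
      rangeT1 = as.numeric(rangeT1), rangeFlair = as.numeric(rangeFlair),
      rangeMode = rangeMode)
}

#' Derive a frozen binning from pooled control intensities
#'
#' The per-contrast range is [0, headroom x P] where P is the
#' \code{percentile} quantile (default 99.9) of the pooled control
#' intensities. The headroom factor (default 2) leaves room for subjects
#' whose arbitrary scanner units exceed the control scale, so their
#' histograms are not truncated before affine alignment can correct the
#' scale. Once built into an atlas the binning is frozen for all subjects.
#'
#' @param controls list of \linkS4class{PairedIntensities} (the control pool)
#' @param nBins bins per axis
#' @param percentile robust upper percentile (0-100 scale)
#' @param headroom multiplier on the upper range limit
#' @return a \linkS4class{BinningSpec} with rangeMode "robust_percentile"
#' @export
robustBinning <- function(controls, nBins = 256L, percentile = 99.9,
                          headroom = 2) {
  stopifnot(length(controls) >= 1L)
  t1 <- unlist(lapply(controls, function(p) p@t1))
  fl <- unlist(lapply(controls, function(p) p@flair))
  hiT1 <- headroom * quantile(t1, percentile / 100, names = FALSE)
  hiFl <- headroom * quantile(fl, percentile / 100, names = FALSE)
  binningSpec(nBins, nBins, c(0, hiT1), c(0, hiFl),
              rangeMode = "robust_percentile")
}

.edges <- function(spec) {
  list(t1 = seq(spec@rangeT1[1], spec@rangeT1[2],
                length.out = spec@nBinsT1 + 1L),
       flair = seq(spec@rangeFlair[1], spec@rangeFlair[2],
                   length.out = spec@nBinsFlair + 1L))
}

.binCenters <- function(edges) (head(edges, -1L) + tail(edges, -1L)) / 2

#' Build a bivariate (T1w x FLAIR) intensity histogram
#'
#' Out-of-range values (including negatives) are clipped into the boundary
#' bins, so the counts conserve the voxel count exactly.
#'
#' @param vals a \linkS4class{PairedIntensities}
#' @param spec a \linkS4class{BinningSpec}
#' @param minVoxels too-few-voxels guard (default 1000)
#' @return a raw-count \linkS4class{BivariateHistogram}
#' @export
buildBivariateHistogram <- function(vals, spec, minVoxels = 1000L) {
  stopifnot(is(vals, "PairedIntensities"), is(spec, "BinningSpec"))
  n <- nVoxels(vals)
  if (n < minVoxels)
    stop("too few voxels (", n, " < ", minVoxels, ") to build a histogram")
  e <- .edges(spec)
  i <- findInterval(vals@t1, e$t1, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(vals@flair, e$flair, rightmost.closed = TRUE,
                    all.inside = TRUE)
  cnt <- tabulate((j - 1L) * spec@nBinsT1 + i,
                  nbins = spec@nBinsT1 * spec@nBinsFlair)
  new("BivariateHistogram",
      counts = matrix(as.numeric(cnt), spec@nBinsT1, spec@nBinsFlair),
      edgesT1 = e$t1, edgesFlair = e$flair, nTotal = as.numeric(n),
      normalized = FALSE)
}

#' Normalize a histogram to unit mass
#'
#' @param h a \linkS4class{BivariateHistogram}
#' @return the histogram with counts summing to 1; \code{nTotal} preserved
#' @export
normalizeHistogram <- function(h) {
  stopifnot(is(h, "BivariateHistogram"))
  if (h@normalized) return(h)
  s <- sum(h@counts)
  if (s <= 0) stop("cannot normalize an empty histogram")
  initialize(h, counts = h@counts / s, normalized = TRUE)
}

#' Marginalize a bivariate histogram onto one contrast
#'
#' @param h a \linkS4class{BivariateHistogram}
#' @param axis "t1" or "flair"
#' @return list with \code{edges}, \code{mids} and \code{counts}; the
#'   marginal counts sum to the bivariate total
#' @export
marginalizeHistogram <- function(h, axis = c("t1", "flair")) {
  stopifnot(is(h, "BivariateHistogram"))
  axis <- match.arg(axis)
  if (axis == "t1")
    list(edges = h@edgesT1, mids = .binCenters(h@edgesT1),
         counts = rowSums(h@counts))
  else
    list(edges = h@edgesFlair, mids = .binCenters(h@edgesFlair),
         counts = colSums(h@counts))
}

## Separable Gaussian smoothing of a 2D histogram. The convolution matrix is
## a row-normalized banded Toeplitz (kernel truncated at 4 sigma), so mass at
## the array border is renormalized rather than lost.
.gaussSmoothMat <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + r + 1L]
  }
  K / rowSums(K)
}

.smoothCounts <- function(M, sigma) {
  if (sigma <= 0) return(M)
  Kr <- .gaussSmoothMat(nrow(M), sigma)
  Kc <- .gaussSmoothMat(ncol(M), sigma)
  Kr %*% M %*% t(Kc)
}

## steepest-ascent hill climb to the nearest local maximum (8-neighborhood)
.hillClimb <- function(S, i, j, maxSteps = 10000L) {
  n1 <- nrow(S); n2 <- ncol(S)
  for (s in seq_len(maxSteps)) {
    ii <- max(1L, i - 1L):min(n1, i + 1L)
    jj <- max(1L, j - 1L):min(n2, j + 1L)
    nb <- S[ii, jj, drop = FALSE]
    w <- arrayInd(which.max(nb), dim(nb))
    bi <- ii[w[1]]; bj <- jj[w[2]]
    if (bi == i && bj == j) break
    i <- bi; j <- bj
  }
  c(i, j)
}

## Fig-1-like normative peak loci used as default centroid seeds
.DEFAULT_LOCI <- list(
  t1 = c(CSF = 200, GM = 600, WM = 1000),
  flair = c(CSF = 200, WM = 700, GM = 1100))

#' Build the normative reference atlas from control histograms
#'
#' The reference is the normalized arithmetic mean of the normalized control
#' histograms (so each control contributes equally regardless of brain size).
#' CSF/GM/WM centroids are found by seeded local-maximum search on the
#' Gaussian-smoothed reference: from each seed locus the search hill-climbs
#' to the nearest mode. The LESION centroid has no control mode and is placed
#' at t1 = midpoint of the GM/WM t1 centroids, flair = GM flair centroid +
#' 1.5 x (GM - WM flair gap), unless supplied in \code{centroidInit}.
#'
#' @param controlHistograms list of \linkS4class{BivariateHistogram} on one
#'   identical binning (>= 2)
#' @param centroidInit optional named list with elements \code{t1} and
#'   \code{flair} giving CSF/GM/WM seed loci in intensity units, and
#'   optionally \code{lesion = c(t1, flair)} to override the lesion locus
#' @param binning the \linkS4class{BinningSpec} the histograms were built on
#' @param smoothSigma smoothing for mode finding, in bins (default 2)
#' @return a \linkS4class{ReferenceAtlas}; errors if the recovered centroids
#'   violate the normative ordering constraints (pathological control set)
#' @export
buildReferenceAtlas <- function(controlHistograms, centroidInit = NULL,
                                binning = NULL, smoothSigma = 2) {
  stopifnot(length(controlHistograms) >= 2L)
  h1 <- controlHistograms[[1L]]
  for (h in controlHistograms[-1L])
    if (!isTRUE(all.equal(h@edgesT1, h1@edgesT1)) ||
        !isTRUE(all.equal(h@edgesFlair, h1@edgesFlair)))
      stop("binning mismatch: all control histograms must share one binning")
  if (is.null(binning))
    binning <- binningSpec(nrow(h1@counts), ncol(h1@counts),
                           range(h1@edgesT1), range(h1@edgesFlair))
  norm <- lapply(controlHistograms, normalizeHistogram)
  mean_counts <- Reduce(`+`, lapply(norm, histCounts)) / length(norm)
  mean_counts <- mean_counts / sum(mean_counts)
  ref <- new("BivariateHistogram", counts = mean_counts,
             edgesT1 = h1@edgesT1, edgesFlair = h1@edgesFlair,
             nTotal = 1, normalized = TRUE)

  loci <- .DEFAULT_LOCI
  if (!is.null(centroidInit)) {
    if (!is.null(centroidInit$t1)) loci$t1 <- centroidInit$t1
    if (!is.null(centroidInit$flair)) loci$flair <- centroidInit$flair
  }
  S <- .smoothCounts(mean_counts, smoothSigma)
  midT1 <- .binCenters(h1@edgesT1)
  midFl <- .binCenters(h1@edgesFlair)
  seedBin <- function(t1v, flv)
    c(which.min(abs(midT1 - t1v)), which.min(abs(midFl - flv)))
  cc <- matrix(NA_real_, 4, 2, dimnames = list(.TISSUES, c("t1", "flair")))
  for (cl in c("CSF", "GM", "WM")) {
    sb <- seedBin(loci$t1[[cl]], loci$flair[[cl]])
    m <- .hillClimb(S, sb[1], sb[2])
    cc[cl, ] <- c(midT1[m[1]], midFl[m[2]])
  }
  if (!is.null(centroidInit$lesion)) {
    cc["LESION", ] <- centroidInit$lesion
  } else {
    cc["LESION", 1] <- mean(cc[c("GM", "WM"), 1])
    cc["LESION", 2] <- cc["GM", 2] + 1.5 * (cc["GM", 2] - cc["WM", 2])
  }
  atlas <- try(new("ReferenceAtlas", reference = ref, classCentroids = cc,
                   nControls = length(controlHistograms), binning = binning),
               silent = TRUE)
  if (inherits(atlas, "try-error"))
    stop("centroid ordering violation (pathological control set): ",
         attr(atlas, "condition")$message)
  atlas
}

#' Serialize / load a reference atlas archive
#'
#' The atlas (reference counts, bin edges, class centroids, binning) is
#' written as a single JSON archive loadable by the alignment and
#' segmentation stages.
#'
#' @param atlas a \linkS4class{ReferenceAtlas}
#' @param path output path (.json)
#' @return \code{writeAtlas}: the path, invisibly. \code{readAtlas}: the
#'   \linkS4class{ReferenceAtlas}.
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "ReferenceAtlas"))
  ref <- atlas@reference
  obj <- list(
    format = "histnorm-atlas-v1",
    n_controls = atlas@nControls,
    binning = list(n_bins_t1 = atlas@binning@nBinsT1,
                   n_bins_flair = atlas@binning@nBinsFlair,
                   range_t1 = atlas@binning@rangeT1,
                   range_flair = atlas@binning@rangeFlair,
                   range_mode = atlas@binning@rangeMode),
    edges_t1 = ref@edgesT1, edges_flair = ref@edgesFlair,
    class_centroids = lapply(seq_len(4), function(i)
      as.numeric(atlas@classCentroids[i, ])),
    classes = .TISSUES,
    reference_counts = as.numeric(ref@counts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeAtlas
#' @export
readAtlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "histnorm-atlas-v1"))
    stop("not a histnorm atlas archive: ", path)
  b <- obj$binning
  spec <- binningSpec(b$n_bins_t1, b$n_bins_flair, b$range_t1, b$range_flair,
                      rangeMode = b$range_mode)
  cc <- obj$class_centroids
  if (is.list(cc)) cc <- do.call(rbind, cc)
  cc <- matrix(as.numeric(cc), ncol = 2,
               dimnames = list(obj$classes, c("t1", "flair")))
  ref <- new("BivariateHistogram",
             counts = matrix(obj$reference_counts, b$n_bins_t1,
                             b$n_bins_flair),
             edgesT1 = obj$edges_t1, edgesFlair = obj$edges_flair,
             nTotal = 1, normalized = TRUE)
  new("ReferenceAtlas", reference = ref, classCentroids = cc,
      nControls = as.integer(obj$n_controls), binning = spec)
}
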