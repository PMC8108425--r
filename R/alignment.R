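#' Construct, invert and compose intensity-plane affine transforms
#'
#' \code{intensityAffine(A, b)} maps a subject-space intensity pair x =
#' (t1, flair) to reference space via x' = A x + b.
#'
#' @param linear 2x2 matrix A with det(A) > 0
#' @param offset length-2 vector b (intensity units)
#' @return an \linkS4class{IntensityAffine}
#' @export
intensityAffine <- function(linear = diag(2), offset = c(0, 0)) {
  new("IntensityAffine", linear = matrix(as.numeric(linear), 2, 2),
      offset = as.numeric(offset))
}

#' @rdname intensityAffine
#' @param t,t1,t2 \linkS4class{IntensityAffine} objects
#' @export
invertAffine <- function(t) {
  Ai <- solve(t@linear)
  intensityAffine(Ai, -Ai %*% t@offset)
}

#' @rdname intensityAffine
#' @details \code{composeAffine(t2, t1)} is the map applying t1 first, then
#'   t2: x -> t2(t1(x)).
#' @export
composeAffine <- function(t2, t1) {
  intensityAffine(t2@linear %*% t1@linear,
                  t2@linear %*% t1@offset + t2@offset)
}

#' Serialize / load an intensity transform as JSON
#'
#' @param t an \linkS4class{IntensityAffine}
#' @param path output path
#' @return \code{writeIntensityAffine}: the path, invisibly;
#'   \code{readIntensityAffine}: the transform
#' @export
writeIntensityAffine <- function(t, path) {
  jsonlite::write_json(list(convention = "x_ref = A %*% x_subject + b",
                            A = apply(t@linear, 1, as.numeric,
                                      simplify = FALSE),
                            b = t@offset),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeIntensityAffine
#' @export
readIntensityAffine <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  intensityAffine(matrix(t(obj$A), 2, 2, byrow = TRUE), obj$b)
}

#' Default optimizer settings for histogram registration
#'
#' Derivative-free Nelder-Mead simplex from five fixed multi-starts
#' (identity plus +/-10 percent single-axis scalings), iteration cap and
#' relative tolerance on the dissimilarity functional; no randomness
#' anywhere, so registration is deterministic.
#'
#' @param smoothSigma Gaussian smoothing of both histograms before the
#'   square-root transform, in bins
#' @param maxit Nelder-Mead iteration cap per start
#' @param reltol relative convergence tolerance on the functional
#' @param qcThreshold alignment-error QC threshold recorded on the result
#'   (\code{Inf} = decide later with \code{\link{qcGate}})
#' @param coarseFactor coarse-to-fine pyramid: each multi-start is first
#'   optimized on a histogram downsampled by this factor (cheap, smooth
#'   landscape), then refined at full resolution; 1 disables the pyramid.
#'   Requires the bin counts to be divisible by the factor.
#' @return a list of settings
#' @export
registrationOptions <- function(smoothSigma = 2, maxit = 2000,
                                reltol = 1e-8, qcThreshold = Inf,
                                coarseFactor = 4L) {
  list(smoothSigma = smoothSigma, maxit = maxit, reltol = reltol,
       qcThreshold = qcThreshold, coarseFactor = as.integer(coarseFactor))
}

## sum f x f blocks of a matrix (histogram downsampling)
.aggregateCounts <- function(M, f) {
  n1 <- nrow(M) %/% f
  n2 <- ncol(M) %/% f
  g1 <- rep(seq_len(n1), each = f)
  g2 <- rep(seq_len(n2), each = f)
  t(rowsum(t(rowsum(M, g1)), g2))
}

.MULTISTARTS <- list(c(1, 1), c(1.1, 1), c(0.9, 1), c(1, 1.1), c(1, 0.9))

## Shared preparation: normalized, smoothed subject mass and sqrt reference
## mass on the atlas grid. Subject must be histogrammed on the atlas binning.
.prepRegistration <- function(subject, atlas, smoothSigma) {
  ref <- atlas@reference
  if (!isTRUE(all.equal(subject@edgesT1, ref@edgesT1)) ||
      !isTRUE(all.equal(subject@edgesFlair, ref@edgesFlair)))
    stop("subject histogram is not on the atlas binning")
  sm <- normalizeHistogram(subject)@counts
  if (sum(sm > 0) < 2L)
    stop("degenerate histogram: a single occupied bin cannot be registered")
  list(subj = .smoothCounts(sm, smoothSigma),
       refSqrt = sqrt(.smoothCounts(ref@counts, smoothSigma)),
       cT1 = .binCenters(ref@edgesT1), cFl = .binCenters(ref@edgesFlair))
}

.parToAffine <- function(par, w1, w2)
  intensityAffine(matrix(par[1:4], 2, 2, byrow = TRUE),
                  c(par[5] * w1, par[6] * w2))

#' Register a subject bivariate histogram to the reference atlas
#'
#' Finds the 6-parameter 2D affine transform of the intensity plane that
#' minimizes the dissimilarity functional — sum of squared differences
#' between the normalized, Gaussian-smoothed, square-root-transformed
#' subject histogram (pushed forward through the transform with Jacobian
#' correction) and the reference. The functional value at the optimum is
#' the subject's alignment error, used downstream for QC.
#'
#' @param subject \linkS4class{BivariateHistogram} on the atlas binning
#' @param atlas \linkS4class{ReferenceAtlas}
#' @param opts settings from \code{\link{registrationOptions}}
#' @return an \linkS4class{AlignmentResult}
#' @export
registerHistogram <- function(subject, atlas, opts = registrationOptions()) {
  prep <- .prepRegistration(subject, atlas, opts$smoothSigma)
  w1 <- prep$cT1[2] - prep$cT1[1]
  w2 <- prep$cFl[2] - prep$cFl[1]
  ## offsets are parameterized in full-resolution bin widths so the same
  ## parameter vector is valid at every pyramid level
  fn <- function(par)
    hn_affine_ssd(prep$subj, prep$refSqrt, prep$cT1, prep$cFl,
                  c(par[1:4], par[5] * w1, par[6] * w2))
  f <- opts$coarseFactor
  fnCoarse <- NULL
  if (!is.null(f) && f > 1L && nrow(prep$subj) %% f == 0L &&
      ncol(prep$subj) %% f == 0L) {
    ref <- atlas@reference
    subC <- .smoothCounts(.aggregateCounts(normalizeHistogram(subject)@counts,
                                           f), opts$smoothSigma)
    refC <- sqrt(.smoothCounts(.aggregateCounts(ref@counts, f),
                               opts$smoothSigma))
    cT1c <- .binCenters(ref@edgesT1[seq(1, length(ref@edgesT1), by = f)])
    cFlc <- .binCenters(ref@edgesFlair[seq(1, length(ref@edgesFlair),
                                           by = f)])
    fnCoarse <- function(par)
      hn_affine_ssd(subC, refC, cT1c, cFlc,
                    c(par[1:4], par[5] * w1, par[6] * w2))
  }
  ## every start is evaluated and (if the pyramid is on) optimized at the
  ## coarse level; the most promising start is refined at full resolution.
  ## The returned optimum always dominates every raw start, including exact
  ## identity for self-registration.
  best <- NULL
  seeds <- list()
  for (s in .MULTISTARTS) {
    par0 <- c(s[1], 0, 0, s[2], 0, 0)
    f0 <- fn(par0)
    if (is.null(best) || f0 < best$value)
      best <- list(par = par0, value = f0, conv = TRUE, counts = 0L)
    nEval <- 0L
    if (!is.null(fnCoarse)) {
      cfit <- optim(par0, fnCoarse, method = "Nelder-Mead",
                    control = list(maxit = opts$maxit,
                                   reltol = opts$reltol))
      par0 <- cfit$par
      nEval <- as.integer(cfit$counts[["function"]])
    }
    seeds[[length(seeds) + 1L]] <- list(par = par0, value = fn(par0),
                                        counts = nEval)
  }
  top <- seeds[[which.min(vapply(seeds, `[[`, numeric(1), "value"))]]
  fit <- optim(top$par, fn, method = "Nelder-Mead",
               control = list(maxit = opts$maxit, reltol = opts$reltol))
  if (fit$value < best$value)
    best <- list(par = fit$par, value = fit$value,
                 conv = fit$convergence == 0L,
                 counts = top$counts +
                   as.integer(fit$counts[["function"]]))
  if (!best$conv)
    warning("registration did not converge within ", opts$maxit,
            " iterations; reporting best transform found")
  new("AlignmentResult", transform = .parToAffine(best$par, w1, w2),
      error = best$value, converged = best$conv,
      nIterations = best$counts,
      qcPass = best$value <= opts$qcThreshold,
      qcThreshold = opts$qcThreshold)
}

#' Alignment error of a given transform
#'
#' Evaluates the registration dissimilarity functional for an arbitrary
#' transform; zero iff the transformed subject histogram equals the
#' reference exactly.
#'
#' @inheritParams registerHistogram
#' @param t an \linkS4class{IntensityAffine}
#' @param smoothSigma histogram smoothing in bins (match the value used at
#'   registration time for comparable numbers)
#' @return non-negative scalar
#' @export
alignmentError <- function(subject, atlas, t, smoothSigma = 2) {
  prep <- .prepRegistration(subject, atlas, smoothSigma)
  A <- t@linear
  hn_affine_ssd(prep$subj, prep$refSqrt, prep$cT1, prep$cFl,
                c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t@offset))
}

#' Alignment-error QC gate
#'
#' Partitions subjects into kept and excluded by alignment error against a
#' fixed criterion, mirroring the study design in which subjects whose
#' histograms could not be affinely matched to the reference were dropped.
#' With \code{threshold = "auto"} the criterion is median + 4 x MAD of the
#' error distribution — a robust-outlier surrogate for a visually chosen
#' fixed criterion, always overridable with a numeric threshold.
#'
#' @param results list of \linkS4class{AlignmentResult}, optionally named by
#'   subject id
#' @param threshold numeric, or "auto"
#' @param plotFile optional path; if given, the error histogram with the
#'   threshold line is written there (PDF) for visual inspection
#' @return list with \code{kept}, \code{excluded} (ids), \code{threshold},
#'   and the error vector \code{errors}
#' @export
qcGate <- function(results, threshold = "auto", plotFile = NULL) {
  stopifnot(length(results) >= 1L)
  errs <- vapply(results, alignError, numeric(1))
  ids <- names(results)
  if (is.null(ids)) ids <- as.character(seq_along(results))
  if (identical(threshold, "auto"))
    threshold <- median(errs) + 4 * mad(errs)
  keep <- errs <= threshold
  if (!is.null(plotFile)) {
    grDevices::pdf(plotFile, width = 6, height = 4)
    on.exit(grDevices::dev.off())
    graphics::hist(errs, breaks = 30, main = "Histogram alignment error",
                   xlab = "alignment error", col = "grey80")
    graphics::abline(v = threshold, col = "red", lwd = 2)
  }
  list(kept = ids[keep], excluded = ids[!keep], threshold = threshold,
       errors = setNames(errs, ids))
}

#' Apply an intensity transform voxelwise
#'
#' Maps every in-mask voxel's (t1, flair) intensity pair through the
#' transform, producing the standardized images whose bivariate histogram
#' approximates the normative reference. Off-mask voxels are zeroed; the
#' mask itself is unchanged.
#'
#' @param pair a \linkS4class{VolumePair}
#' @param t an \linkS4class{IntensityAffine} (subject -> reference)
#' @return a standardized \linkS4class{VolumePair}
#' @export
applyIntensityTransform <- function(pair, t) {
  stopifnot(is(pair, "VolumePair"), is(t, "IntensityAffine"))
  validObject(t)   # non-invertible transforms rejected by validity
  idx <- which(pair@brainMask != 0)
  X <- rbind(pair@t1w[idx], pair@flair[idx])
  Y <- t@linear %*% X + t@offset
  t1 <- array(0, dim = dim(pair@t1w))
  fl <- array(0, dim = dim(pair@flair))
  t1[idx] <- Y[1, ]
  fl[idx] <- Y[2, ]
  volumePair(t1, fl, pair@brainMask, voxelSize = pair@voxelSize,
             subjectId = pair@subjectId, standardized = TRUE)
}
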