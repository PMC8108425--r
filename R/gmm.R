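## Weighted EM engine shared by the voxel-sample and binned-histogram paths.
## Deterministic: seeds come in, no randomness; log-likelihood is tracked per
## iteration (it must be non-decreasing, a property the tests assert).
.emFit <- function(x, w, mu, sigma, weight, maxIter = 500L, tol = 1e-7,
                   sigmaFloor = NULL, minWeight = 1e-4, assign = NULL) {
  k <- length(mu)
  stopifnot(length(sigma) == k, length(weight) == k)
  weight <- weight / sum(weight)
  if (is.null(sigmaFloor)) sigmaFloor <- 1e-3 * diff(range(x))
  sigma <- pmax(sigma, sigmaFloor)
  n <- sum(w)
  forced <- !is.null(assign) && any(assign > 0L)
  if (forced) {
    fi <- which(assign > 0L)
    fj <- assign[fi]
  }
  llTrace <- numeric(0)
  llOld <- -Inf
  converged <- FALSE
  dens <- matrix(0, length(x), k)
  for (iter in seq_len(maxIter)) {
    for (j in seq_len(k)) dens[, j] <- weight[j] * dnorm(x, mu[j], sigma[j])
    s <- rowSums(dens)
    if (forced) s[fi] <- pmax(dens[cbind(fi, fj)], .Machine$double.xmin)
    s[s < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(w * log(s))
    llTrace <- c(llTrace, ll)
    resp <- dens / s
    if (forced) {
      resp[fi, ] <- 0
      resp[cbind(fi, fj)] <- 1
    }
    Nk <- colSums(w * resp)
    if (any(Nk / n < minWeight))
      stop("degenerate fit: component weight below ", minWeight,
           " (components may have merged or a seed found no support)")
    weight <- Nk / n
    mu <- colSums(w * resp * x) / Nk
    for (j in seq_len(k))
      sigma[j] <- sqrt(sum(w * resp[, j] * (x - mu[j])^2) / Nk[j])
    sigma <- pmax(sigma, sigmaFloor)
    if (is.finite(llOld) && abs(ll - llOld) / n < tol) {
      converged <- TRUE
      break
    }
    llOld <- ll
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations")
  list(mu = mu, sigma = sigma, weight = weight, logLik = ll,
       llTrace = llTrace, iterations = iter, converged = converged)
}

## re-sort components by mu and attach seed identities by mu rank
.labelComponents <- function(fit, seedMu, quietOverlap = FALSE) {
  ord <- order(fit$mu)
  comp <- data.frame(mu = fit$mu[ord], sigma = fit$sigma[ord],
                     weight = fit$weight[ord])
  if (!is.null(names(seedMu)))
    rownames(comp) <- names(seedMu)[order(seedMu)]
  if (nrow(comp) > 1 && !quietOverlap) {
    sep <- diff(comp$mu) /
      (head(comp$sigma, -1) + tail(comp$sigma, -1))
    if (any(sep < 1.25))
      warning("merged components: adjacent fitted means are separated by ",
              "less than 1.25 pooled sigmas; the mixture is not ",
              "identifiable at this seeding")
  }
  comp
}

#' Fit a univariate Gaussian mixture by seeded, deterministic EM
#'
#' EM on the raw sample (or, via \code{weights}, on binned values) with
#' seeds supplied by the caller — in the pipeline, always the atlas class
#' loci, so fitting is deterministic and component identity is meaningful.
#' Components are re-sorted by mean after fitting and matched to seed
#' identity by mu ordering. Sigmas are floored at 1e-3 of the data range.
#'
#' @param values numeric sample (>= 100 values when unweighted)
#' @param init list with \code{mu} (optionally named by tissue class),
#'   \code{sigma} and \code{weight}, all length k
#' @param weights optional non-negative weights (e.g. bin counts when
#'   \code{values} are bin centers: the binned fast path)
#' @param hardAssign optional integer vector (one per value): 0 leaves the
#'   value free, j > 0 fixes its responsibility to component j
#'   (semi-supervised EM for values whose class membership is known, e.g.
#'   segmented lesion voxels that belong to the WM tissue class)
#' @param maxIter,tol EM stopping rule: log-likelihood change per sample
#'   below \code{tol} (default 1e-7) or \code{maxIter} (default 500)
#' @return list with \code{components} (data.frame mu/sigma/weight, rows in
#'   mu order carrying seed names), \code{logLik}, \code{llTrace},
#'   \code{iterations}, \code{converged}
#' @export
fitUnivariateGMM <- function(values, init, weights = NULL,
                             hardAssign = NULL, maxIter = 500L,
                             tol = 1e-7) {
  stopifnot(is.list(init), length(init$mu) >= 1L)
  if (is.null(weights)) {
    if (length(values) < 100L)
      stop("need at least 100 values to fit a mixture")
    weights <- rep(1, length(values))
  }
  if (is.null(init$sigma)) init$sigma <- rep(diff(range(values)) / 10,
                                             length(init$mu))
  if (is.null(init$weight)) init$weight <- rep(1, length(init$mu))
  fit <- .emFit(values, weights, as.numeric(init$mu),
                as.numeric(init$sigma), as.numeric(init$weight),
                maxIter = maxIter, tol = tol, assign = hardAssign)
  ## overlap between a hard-assigned component and its neighbours is by
  ## construction, not an identifiability failure
  quiet <- !is.null(hardAssign) && any(hardAssign > 0L)
  out <- list(components = .labelComponents(fit, init$mu, quiet),
              logLik = fit$logLik, llTrace = fit$llTrace,
              iterations = fit$iterations, converged = fit$converged)
  class(out) <- "gmmFit"
  out
}

#' @export
print.gmmFit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d components, logLik = %.4g, %s\n",
              nrow(x$components), x$logLik,
              if (x$converged) sprintf("converged in %d iterations",
                                       x$iterations)
              else "NOT converged"))
  print(round(x$components, 4))
  invisible(x)
}

## deterministic stride thinning for large voxel samples
.thin <- function(idx, maxN) {
  if (length(idx) <= maxN) return(idx)
  idx[round(seq(1, length(idx), length.out = maxN))]
}

## atlas-seeded init for one contrast; classes in mu order for that contrast
.contrastInit <- function(atlas, contrast, classes, labelSD, labelFrac) {
  cc <- atlas@classCentroids[, contrast]
  mu <- cc[classes]
  sigma <- labelSD[classes]
  sigma[!is.finite(sigma) | sigma <= 0] <- diff(range(mu)) / 10
  weight <- labelFrac[classes]
  weight[!is.finite(weight) | weight <= 0] <- 0.01
  list(mu = mu, sigma = sigma, weight = weight / sum(weight))
}

#' Extract the per-subject GMM signal parameters
#'
#' Fits a univariate Gaussian mixture to the pooled in-scope standardized
#' intensities of each contrast, seeded at the atlas class loci, and reports
#' the eight analyzed parameters: mu and sigma of the GM and WM components
#' on T1w and FLAIR. The label map gates the in-scope voxel set: with
#' \code{variant = "lesions_excluded"} LESION voxels are dropped before
#' fitting; with \code{"lesions_included"} they are kept and — because a
#' white-matter lesion is white-matter tissue — hard-assigned to the WM
#' component (semi-supervised EM), so lesion burden widens the WM Gaussian
#' exactly as including lesions in the WM class should. Component identity
#' is fixed by the atlas mu ordering, never by fit order. The CSF component
#' is carried along but not analyzed.
#'
#' @param pair standardized \linkS4class{VolumePair}
#' @param labelMap \linkS4class{TissueLabelMap} from
#'   \code{\link{classifyTissues}}
#' @param atlas \linkS4class{ReferenceAtlas}
#' @param variant "lesions_excluded" (default) or "lesions_included"
#' @param maxVoxelsFit deterministic stride-thinning cap on the EM sample
#' @param binned use the binned-histogram EM fast path (responsibilities
#'   weighted by bin counts) instead of the voxel sample; the two paths
#'   agree to a fraction of a percent on all parameters
#' @return a \linkS4class{SubjectParameters}
#' @export
extractSubjectParameters <- function(pair, labelMap, atlas,
                                     variant = c("lesions_excluded",
                                                 "lesions_included"),
                                     maxVoxelsFit = 50000L, binned = FALSE) {
  variant <- match.arg(variant)
  stopifnot(is(pair, "VolumePair"), is(labelMap, "TissueLabelMap"))
  lab3d <- labelMap@labels
  idx <- which(lab3d != 0L)
  lab <- lab3d[idx]
  if (variant == "lesions_excluded") {
    keep <- lab != .CODE[["LESION"]]
    idx <- idx[keep]; lab <- lab[keep]
  }
  nLesion <- sum(lab == .CODE[["LESION"]])
  sub <- .thin(seq_along(idx), maxVoxelsFit)
  idx <- idx[sub]; lab <- lab[sub]
  t1 <- pair@t1w[idx]
  fl <- pair@flair[idx]
  frac <- vapply(1:4, function(k) mean(lab == k), numeric(1))
  names(frac) <- .TISSUES
  sdT1 <- vapply(1:4, function(k) sd(t1[lab == k]), numeric(1))
  sdFl <- vapply(1:4, function(k) sd(fl[lab == k]), numeric(1))
  names(sdT1) <- names(sdFl) <- .TISSUES

  ## in the lesions-included variant, lesion-labeled voxels are known WM
  ## tissue: their component membership is fixed rather than estimated
  lesionToWM <- variant == "lesions_included" && nLesion > 0L
  fitOne <- function(x, contrast, classes, labelSD) {
    init <- .contrastInit(atlas, contrast, classes, labelSD, frac)
    ha <- NULL
    if (lesionToWM) {
      ha <- integer(length(x))
      ha[lab == .CODE[["LESION"]]] <- match("WM", classes)
    }
    if (binned) {
      br <- range(x)
      edges <- seq(br[1] - 1e-9, br[2] + 1e-9, length.out = 257L)
      bi <- findInterval(x, edges, all.inside = TRUE)
      if (lesionToWM) {
        cnt <- tabulate(bi[ha == 0L], nbins = 256L)
        lcnt <- tabulate(bi[ha > 0L], nbins = 256L)
        vals2 <- c(.binCenters(edges)[cnt > 0], .binCenters(edges)[lcnt > 0])
        w2 <- c(cnt[cnt > 0], lcnt[lcnt > 0])
        ha2 <- c(integer(sum(cnt > 0)),
                 rep.int(match("WM", classes), sum(lcnt > 0)))
        fitUnivariateGMM(vals2, init, weights = w2, hardAssign = ha2)
      } else {
        cnt <- tabulate(bi, nbins = 256L)
        fitUnivariateGMM(.binCenters(edges), init, weights = cnt)
      }
    } else {
      fitUnivariateGMM(x, init, hardAssign = ha)
    }
  }
  t1Fit <- tryCatch(fitOne(t1, "t1", c("CSF", "GM", "WM"), sdT1),
                    error = function(e) stop("T1 mixture fit failed: ",
                                             conditionMessage(e)))
  flFit <- tryCatch(fitOne(fl, "flair", c("CSF", "WM", "GM"), sdFl),
                    error = function(e) stop("FLAIR mixture fit failed: ",
                                             conditionMessage(e)))
  tc <- t1Fit$components
  fc <- flFit$components
  params <- c(t1_wm_mu = tc["WM", "mu"], t1_gm_mu = tc["GM", "mu"],
              t1_wm_sigma = tc["WM", "sigma"],
              t1_gm_sigma = tc["GM", "sigma"],
              flair_wm_mu = fc["WM", "mu"], flair_gm_mu = fc["GM", "mu"],
              flair_wm_sigma = fc["WM", "sigma"],
              flair_gm_sigma = fc["GM", "sigma"])
  csf <- c(t1_csf_mu = tc["CSF", "mu"], t1_csf_sigma = tc["CSF", "sigma"],
           flair_csf_mu = fc["CSF", "mu"],
           flair_csf_sigma = fc["CSF", "sigma"])
  new("SubjectParameters", subjectId = pair@subjectId, variant = variant,
      parameters = params, csf = csf,
      lesion = lesionMetrics(labelMap, pair, atlas),
      mixtures = list(t1 = tc, flair = fc))
}
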