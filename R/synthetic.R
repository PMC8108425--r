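#' Specification of a synthetic brain phantom
#'
#' Phantom geometry is three concentric ellipsoids — a CSF core, a WM
#' interior and a GM shell — sized so the class proportions are plausible
#' (about 10 / 45 / 45 percent of brain for CSF / WM / GM). The method under
#' test is intensity-statistical, so geometry only needs plausible class
#' proportions, not anatomy. Each class draws (T1w, FLAIR) pairs from a
#' bivariate Gaussian whose default means sit at the normative control peak
#' loci: T1w 200 (CSF), 600 (GM), 1000 (WM); FLAIR 200 (CSF), 700 (WM),
#' 1100 (GM). Discrete hyperintense lesions are spheres seeded inside WM;
#' diffuse NAWM heterogeneity is a per-voxel Gaussian field added to WM
#' FLAIR (zero in controls). A scanner effect — an exact affine map of the
#' intensity plane — emulates arbitrary scanner units.
#'
#' @param shape 3D dimensions (default 48^3)
#' @param voxelSize mm per axis
#' @param classMeans list with named vectors \code{t1} and \code{flair}
#'   (CSF/GM/WM class means, scanner units)
#' @param classSD per-class per-contrast within-class SD (default 50)
#' @param lesionCount number of spherical lesions (default 0)
#' @param lesionRadius integer radius range in voxels, default c(1, 3)
#' @param lesionFlairElevation lesion FLAIR mean elevation above WM; the
#'   default (+1000) places lesions at the atlas lesion locus
#' @param lesionT1Depression lesion T1w mean depression below WM (default
#'   200, the GM/WM midpoint)
#' @param nawmFieldSD SD of the diffuse NAWM FLAIR field (0 = control)
#' @param scannerEffect an \linkS4class{IntensityAffine} applied to every
#'   voxel's intensity pair (default identity)
#' @param noiseSD extra additive Gaussian noise per contrast (default 0;
#'   the class SDs already model within-class variability)
#' @param gammaDistortion optional nonlinearity exponent applied to FLAIR
#'   after the scanner effect (1 = none); a non-affine distortion used to
#'   stress the alignment QC gate
#' @param seed RNG seed: the same seed gives byte-identical phantoms
#' @return a list of class \code{phantomSpec}
#' @export
phantomSpec <- function(shape = c(48L, 48L, 48L), voxelSize = c(1, 1, 1),
                        classMeans = list(
                          t1 = c(CSF = 200, GM = 600, WM = 1000),
                          flair = c(CSF = 200, WM = 700, GM = 1100)),
                        classSD = 50, lesionCount = 0L,
                        lesionRadius = c(1L, 3L),
                        lesionFlairElevation = 1000,
                        lesionT1Depression = 200,
                        nawmFieldSD = 0,
                        scannerEffect = intensityAffine(),
                        noiseSD = 0, gammaDistortion = 1, seed = 1L) {
  spec <- list(shape = as.integer(shape), voxelSize = voxelSize,
               classMeans = classMeans, classSD = classSD,
               lesionCount = as.integer(lesionCount),
               lesionRadius = as.integer(lesionRadius),
               lesionFlairElevation = lesionFlairElevation,
               lesionT1Depression = lesionT1Depression,
               nawmFieldSD = nawmFieldSD, scannerEffect = scannerEffect,
               noiseSD = noiseSD, gammaDistortion = gammaDistortion,
               seed = as.integer(seed))
  class(spec) <- "phantomSpec"
  spec
}

## nested-ellipsoid geometry: radius fractions chosen so class volumes are
## ~10% CSF, ~45% WM, ~45% GM of the brain ellipsoid
.R_CSF <- 0.10^(1 / 3)
.R_WM <- 0.55^(1 / 3)

.phantomGeometry <- function(shape) {
  ctr <- (shape + 1) / 2
  ax <- 0.45 * shape
  ix <- seq_len(shape[1]); iy <- seq_len(shape[2]); iz <- seq_len(shape[3])
  r2 <- outer(outer(((ix - ctr[1]) / ax[1])^2,
                    ((iy - ctr[2]) / ax[2])^2, `+`),
              ((iz - ctr[3]) / ax[3])^2, `+`)
  lab <- array(0L, dim = shape)
  lab[r2 <= 1] <- .CODE[["GM"]]
  lab[r2 <= .R_WM^2] <- .CODE[["WM"]]
  lab[r2 <= .R_CSF^2] <- .CODE[["CSF"]]
  lab
}

#' Generate a synthetic phantom with known ground truth
#'
#' Deterministic given the spec's seed. Returns the volume pair, the
#' ground-truth tissue label map and the exact per-class intensity
#' parameters after the scanner effect, so that end-to-end parameter
#' recovery is checkable against truth.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @return list with \code{pair} (\linkS4class{VolumePair}),
#'   \code{labels} (ground-truth \linkS4class{TissueLabelMap}),
#'   \code{truth} (per-class post-effect means and SDs) and \code{spec}
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  .withSeed(spec$seed, {
    lab <- .phantomGeometry(spec$shape)
    mask <- lab != 0L

    ## lesion placement: spheres fully drawn from current WM voxels
    wmIdx <- which(lab == .CODE[["WM"]])
    if (spec$lesionCount > 0L) {
      radii <- sample(seq(spec$lesionRadius[1], spec$lesionRadius[2]),
                      spec$lesionCount, replace = TRUE)
      expected <- sum(ceiling(4 / 3 * pi * radii^3))
      if (expected > 0.5 * length(wmIdx))
        stop("geometry overflow: requested lesions exceed half the WM volume")
      centers <- arrayInd(sample(wmIdx, spec$lesionCount), spec$shape)
      for (l in seq_len(spec$lesionCount)) {
        r <- radii[l]
        off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
        off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
        vox <- sweep(off, 2, centers[l, ], `+`)
        ok <- vox[, 1] >= 1 & vox[, 1] <= spec$shape[1] &
          vox[, 2] >= 1 & vox[, 2] <= spec$shape[2] &
          vox[, 3] >= 1 & vox[, 3] <= spec$shape[3]
        vi <- vox[ok, , drop = FALSE]
        li <- (vi[, 3] - 1L) * spec$shape[1] * spec$shape[2] +
          (vi[, 2] - 1L) * spec$shape[1] + vi[, 1]
        li <- li[lab[li] == .CODE[["WM"]]]   # lesions live inside WM only
        lab[li] <- .CODE[["LESION"]]
      }
    }

    mt1 <- spec$classMeans$t1
    mfl <- spec$classMeans$flair
    meanT1 <- c(CSF = unname(mt1["CSF"]), GM = unname(mt1["GM"]),
                WM = unname(mt1["WM"]),
                LESION = unname(mt1["WM"]) - spec$lesionT1Depression)
    meanFl <- c(CSF = unname(mfl["CSF"]), GM = unname(mfl["GM"]),
                WM = unname(mfl["WM"]),
                LESION = unname(mfl["WM"]) + spec$lesionFlairElevation)

    t1 <- array(0, dim = spec$shape)
    fl <- array(0, dim = spec$shape)
    for (cl in .TISSUES) {
      idx <- which(lab == .CODE[[cl]])
      if (!length(idx)) next
      t1[idx] <- meanT1[[cl]] + spec$classSD * rnorm(length(idx))
      fl[idx] <- meanFl[[cl]] + spec$classSD * rnorm(length(idx))
    }
    wmNow <- which(lab == .CODE[["WM"]])
    if (spec$nawmFieldSD > 0 && length(wmNow))
      fl[wmNow] <- fl[wmNow] + spec$nawmFieldSD * rnorm(length(wmNow))
    if (spec$noiseSD > 0) {
      inm <- which(mask)
      t1[inm] <- t1[inm] + spec$noiseSD * rnorm(length(inm))
      fl[inm] <- fl[inm] + spec$noiseSD * rnorm(length(inm))
    }

    pair <- volumePair(t1, fl, mask * 1, voxelSize = spec$voxelSize,
                       subjectId = sprintf("phantom_seed%d", spec$seed))
    pair <- applyIntensityTransform(pair, spec$scannerEffect)
    pair@standardized <- FALSE     # scanner units, not atlas units
    if (spec$gammaDistortion != 1) {
      inm <- which(mask)
      fmax <- max(pair@flair[inm])
      pair@flair[inm] <- fmax *
        pmax(pair@flair[inm] / fmax, 0)^spec$gammaDistortion
    }

    ## exact post-effect class parameters
    A <- spec$scannerEffect@linear
    b <- spec$scannerEffect@offset
    truth <- list()
    for (cl in .TISSUES) {
      mu <- A %*% c(meanT1[[cl]], meanFl[[cl]]) + b
      v1 <- spec$classSD^2 + spec$noiseSD^2
      v2 <- spec$classSD^2 + spec$noiseSD^2 +
        if (cl == "WM") spec$nawmFieldSD^2 else 0
      Sg <- A %*% diag(c(v1, v2)) %*% t(A)
      truth[[cl]] <- list(mean = as.numeric(mu), sd = sqrt(diag(Sg)))
    }
    cnt <- vapply(1:4, function(k) sum(lab == k), numeric(1))
    names(cnt) <- .TISSUES
    centroids <- t(vapply(.TISSUES, function(cl) truth[[cl]]$mean,
                          numeric(2)))
    colnames(centroids) <- c("t1", "flair")
    gt <- new("TissueLabelMap", labels = lab, classCounts = cnt,
              centroids = centroids, excluded = integer(),
              converged = TRUE)
    list(pair = pair, labels = gt, truth = truth, spec = spec)
  })
}

#' Specification of a synthetic five-group cohort
#'
#' Each subject carries a latent severity: 0 in controls, higher and more
#' variable in MS, with the three progressive subtypes sharing one effect
#' profile (they were clinically indistinguishable on these measures, and
#' the generator encodes that). Severity drives the group effect directions
#' of the disease: lower T1w WM mean, brighter T1w GM, darker FLAIR WM/GM
#' means, inflated within-class sigmas, a diffuse NAWM FLAIR field, and a
#' Poisson lesion burden. Disability (PDDS), neuroperformance (3 measures),
#' quality-of-life (12 domains) and atrophy covariates are all driven by
#' the same latent severity plus noise.
#'
#' @param nPerGroup named counts for control/RRMS/SPMS/PPMS/PRMS
#' @param shape phantom dimensions per subject
#' @param effect list of effect coefficients per unit severity:
#'   \code{t1WMShift}, \code{t1GMShift}, \code{flairWMShift},
#'   \code{flairGMShift} (intensity units), \code{sigmaScale}
#'   (multiplicative per unit), \code{nawmFieldSD} (units),
#'   \code{lesionRate} (Poisson mean per unit)
#' @param meanJitterSD between-subject SD of each class mean (intensity
#'   units), the anatomical/biological variability every cohort has
#'   independent of disease
#' @param sigmaJitterSD between-subject multiplicative SD of the
#'   within-class sigma
#' @param severityMean,severitySD length-2: (RRMS, progressive) latent
#'   severity distribution
#' @param scannerScaleRange,scannerOffsetRange per-subject random scanner
#'   effect: axis scalings and offsets drawn uniformly from these ranges
#' @param pddsSlope,pddsNoise disability model: pdds =
#'   round(clamp(pddsSlope x severity + noise, 0, 8))
#' @param seed master seed; per-subject seeds derive from it
#' @return a list of class \code{cohortSpec}
#' @export
cohortSpec <- function(nPerGroup = c(control = 50L, RRMS = 50L, SPMS = 20L,
                                     PPMS = 20L, PRMS = 20L),
                       shape = c(36L, 36L, 36L),
                       effect = list(t1WMShift = -30, t1GMShift = 15,
                                     flairWMShift = -15, flairGMShift = -20,
                                     sigmaScale = 0.08, nawmFieldSD = 30,
                                     lesionRate = 8),
                       meanJitterSD = 25, sigmaJitterSD = 0.10,
                       severityMean = c(RRMS = 1, progressive = 2),
                       severitySD = c(RRMS = 0.3, progressive = 0.4),
                       scannerScaleRange = c(0.85, 1.2),
                       scannerOffsetRange = c(-40, 40),
                       pddsSlope = 1.5, pddsNoise = 0.8, seed = 1L) {
  spec <- list(nPerGroup = nPerGroup, shape = as.integer(shape),
               effect = effect, meanJitterSD = meanJitterSD,
               sigmaJitterSD = sigmaJitterSD, severityMean = severityMean,
               severitySD = severitySD,
               scannerScaleRange = scannerScaleRange,
               scannerOffsetRange = scannerOffsetRange,
               pddsSlope = pddsSlope, pddsNoise = pddsNoise,
               seed = as.integer(seed))
  class(spec) <- "cohortSpec"
  spec
}

.GROUPS <- c("control", "RRMS", "SPMS", "PPMS", "PRMS")

#' Generate a synthetic cohort with clinical table
#'
#' Builds one phantom per subject from the group effect profile and emits a
#' clinical table (group, PDDS, neuroperformance and quality-of-life
#' scores, atrophy covariates) driven by the same latent severity, so the
#' full pipeline plus statistical battery can be exercised end to end with
#' known ground truth. Fully seeded: the same spec gives byte-identical
#' volumes and tables.
#'
#' @param spec a \code{\link{cohortSpec}}
#' @param dir optional directory: if given, per-subject NIfTI triplets and
#'   \code{clinical.csv} are written there
#' @return list with \code{subjects} (list of per-subject lists: pair,
#'   labels, truth, group, severity) and \code{clinical} (data.frame)
#' @export
generateCohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohortSpec"))
  groups <- rep(names(spec$nPerGroup), times = spec$nPerGroup)
  n <- length(groups)
  eff <- spec$effect
  .withSeed(spec$seed, {
    sev <- numeric(n)
    for (i in seq_len(n)) {
      sev[i] <- switch(groups[i],
        control = 0,
        RRMS = max(0.2, rnorm(1, spec$severityMean[["RRMS"]],
                              spec$severitySD[["RRMS"]])),
        max(0.2, rnorm(1, spec$severityMean[["progressive"]],
                       spec$severitySD[["progressive"]])))
    }
    subjSeeds <- sample.int(.Machine$integer.max - 1L, n)
    scanScale <- matrix(runif(2 * n, spec$scannerScaleRange[1],
                              spec$scannerScaleRange[2]), n, 2)
    scanOffset <- matrix(runif(2 * n, spec$scannerOffsetRange[1],
                               spec$scannerOffsetRange[2]), n, 2)
    lesions <- rpois(n, eff$lesionRate * sev)
    pdds <- pmin(8, pmax(0, round(spec$pddsSlope * sev +
                                    rnorm(n, 0, spec$pddsNoise))))
    pdds[groups == "control"] <- NA
    npt <- sapply(1:3, function(j) -0.9 * sev + rnorm(n, 0, 0.45))
    colnames(npt) <- paste0("npt_", 1:3)
    qol <- sapply(1:12, function(j) -0.7 * sev + rnorm(n, 0, 0.7))
    colnames(qol) <- paste0("qol_", 1:12)
    clin <- data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      group = groups,
      pdds = pdds,
      bpf = 0.85 - 0.012 * sev + rnorm(n, 0, 0.008),
      gmf = 0.45 - 0.006 * sev + rnorm(n, 0, 0.006),
      wmf = 0.40 - 0.005 * sev + rnorm(n, 0, 0.006),
      thalamic_volume = 15 - 0.6 * sev + rnorm(n, 0, 0.5),
      true_severity = sev,
      stringsAsFactors = FALSE)
    clin <- cbind(clin, npt, qol)

    ## between-subject variability independent of disease: each subject's
    ## class means and within-class sigma jitter around the normative loci
    mJit <- matrix(rnorm(6 * n, 0, spec$meanJitterSD), n, 6)
    sJit <- pmax(0.5, 1 + rnorm(n, 0, spec$sigmaJitterSD))

    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      s <- sev[i]
      ps <- phantomSpec(
        shape = spec$shape,
        classMeans = list(
          t1 = c(CSF = 200 + mJit[i, 1],
                 GM = 600 + mJit[i, 2] + eff$t1GMShift * s,
                 WM = 1000 + mJit[i, 3] + eff$t1WMShift * s),
          flair = c(CSF = 200 + mJit[i, 4],
                    WM = 700 + mJit[i, 5] + eff$flairWMShift * s,
                    GM = 1100 + mJit[i, 6] + eff$flairGMShift * s)),
        classSD = 50 * sJit[i] * (1 + eff$sigmaScale * s),
        lesionCount = lesions[i],
        nawmFieldSD = eff$nawmFieldSD * s,
        scannerEffect = intensityAffine(diag(scanScale[i, ]),
                                        scanOffset[i, ]),
        seed = subjSeeds[i])
      ph <- generatePhantom(ps)
      ph$pair@subjectId <- clin$subject_id[i]
      subjects[[i]] <- list(pair = ph$pair, labels = ph$labels,
                            truth = ph$truth, group = groups[i],
                            severity = s)
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n)) {
        sd_ <- file.path(dir, clin$subject_id[i])
        dir.create(sd_, showWarnings = FALSE)
        writeVolumePair(subjects[[i]]$pair,
                        file.path(sd_, "t1w.nii.gz"),
                        file.path(sd_, "flair.nii.gz"),
                        file.path(sd_, "mask.nii.gz"))
      }
      write.csv(clin, file.path(dir, "clinical.csv"), row.names = FALSE)
    }
    list(subjects = subjects, clinical = clin)
  })
}
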