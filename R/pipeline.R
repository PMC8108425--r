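#' Pipeline configuration
#'
#' Bundles the tunable settings of every stage with documented defaults.
#' Configurations round-trip losslessly through JSON
#' (\code{\link{writePipelineConfig}} / \code{\link{readPipelineConfig}}).
#'
#' @param nBins histogram bins per axis (default 256)
#' @param percentile robust upper percentile for the atlas range
#' @param headroom multiplier on the atlas range upper limit
#' @param registration settings from \code{\link{registrationOptions}}
#' @param qcThreshold numeric alignment-error threshold, or "auto"
#'   (median + 4 x MAD over the processed batch)
#' @param segmentation settings from \code{\link{segmentationOptions}}
#' @param variants which GMM variants to extract per subject
#' @param maxVoxelsFit EM sample cap (deterministic thinning)
#' @param seed seed for the stochastic statistics (splits, folds)
#' @return a list of class \code{pipelineConfig}
#' @export
pipelineConfig <- function(nBins = 256L, percentile = 99.9, headroom = 2,
                           registration = registrationOptions(),
                           qcThreshold = "auto",
                           segmentation = segmentationOptions(),
                           variants = c("lesions_excluded",
                                        "lesions_included"),
                           maxVoxelsFit = 50000L, seed = 1L) {
  cfg <- list(nBins = as.integer(nBins), percentile = percentile,
              headroom = headroom, registration = registration,
              qcThreshold = qcThreshold, segmentation = segmentation,
              variants = variants, maxVoxelsFit = as.integer(maxVoxelsFit),
              seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param config a \code{pipelineConfig}
#' @param path JSON path
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipelineConfig()
  for (nm in names(obj)) cfg[[nm]] <- obj[[nm]]
  cfg$nBins <- as.integer(cfg$nBins)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Build the normative reference atlas from control volume pairs
#'
#' Derives the frozen binning from the pooled control intensities, builds
#' each control's bivariate histogram on it, and averages them into the
#' reference atlas (see \code{\link{buildReferenceAtlas}}).
#'
#' @param controlPairs list of >= 2 control \linkS4class{VolumePair}s
#' @param config a \code{\link{pipelineConfig}}
#' @param centroidInit optional centroid seed override
#' @return a \linkS4class{ReferenceAtlas}
#' @export
buildAtlas <- function(controlPairs, config = pipelineConfig(),
                       centroidInit = NULL) {
  if (length(controlPairs) < 2L)
    stop("need at least 2 usable control subjects to build an atlas")
  vals <- lapply(controlPairs, extractPairedIntensities)
  spec <- robustBinning(vals, nBins = config$nBins,
                        percentile = config$percentile,
                        headroom = config$headroom)
  hists <- lapply(vals, buildBivariateHistogram, spec = spec)
  buildReferenceAtlas(hists, centroidInit = centroidInit, binning = spec)
}

#' Process one subject through the standardization pipeline
#'
#' Chains the per-subject stages: bivariate histogram on the atlas binning,
#' affine registration to the reference, voxelwise intensity
#' standardization, tissue classification, and GMM parameter extraction for
#' the requested variants. QC failure does not halt processing: parameters
#' are still emitted, flagged by \code{qc_pass} in the output row.
#'
#' @param pair a \linkS4class{VolumePair}
#' @param atlas the \linkS4class{ReferenceAtlas}
#' @param config a \code{\link{pipelineConfig}}; a numeric
#'   \code{qcThreshold} is applied here ("auto" defers to
#'   \code{\link{qcGate}} over a batch)
#' @param outputDir optional directory for per-subject outputs
#'   (transform JSON, label map NIfTI, standardized volumes, parameter CSV)
#' @return list with \code{alignment}, \code{standardized}, \code{labels},
#'   \code{parameters} (list per variant), \code{lesions}, and \code{row}
#'   (tidy one-row-per-variant data.frame)
#' @export
processSubject <- function(pair, atlas, config = pipelineConfig(),
                           outputDir = NULL) {
  h <- buildBivariateHistogram(extractPairedIntensities(pair),
                               binning(atlas))
  ropts <- config$registration
  if (is.numeric(config$qcThreshold))
    ropts$qcThreshold <- config$qcThreshold
  al <- registerHistogram(h, atlas, ropts)
  std <- applyIntensityTransform(pair, alignTransform(al))
  lm_ <- classifyTissues(std, atlas, config$segmentation)
  params <- list()
  rows <- list()
  for (v in config$variants) {
    lv <- if (v == "lesions_excluded") excludeLesions(lm_) else lm_
    sp <- extractSubjectParameters(std, lv, atlas, variant = v,
                                   maxVoxelsFit = config$maxVoxelsFit)
    params[[v]] <- sp
    r <- as.data.frame(sp)
    r$alignment_error <- alignError(al)
    r$qc_pass <- al@qcPass
    rows[[v]] <- r
  }
  row <- do.call(rbind, rows)
  rownames(row) <- NULL
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeIntensityAffine(alignTransform(al),
                         file.path(outputDir, "transform.json"))
    writeLabelMap(lm_, file.path(outputDir, "labels.nii.gz"),
                  voxelSize = pair@voxelSize)
    writeVolumePair(std, file.path(outputDir, "t1w_standardized.nii.gz"),
                    file.path(outputDir, "flair_standardized.nii.gz"))
    write.csv(row, file.path(outputDir, "parameters.csv"),
              row.names = FALSE)
  }
  list(alignment = al, standardized = std, labels = lm_,
       parameters = params,
       lesions = lesionMetrics(lm_, std, atlas), row = row)
}

.GMM_PARAMS <- c("t1_wm_mu", "t1_gm_mu", "t1_wm_sigma", "t1_gm_sigma",
                 "flair_wm_mu", "flair_gm_mu", "flair_wm_sigma",
                 "flair_gm_sigma")

#' Run the biomarker-disability statistical battery
#'
#' Joins the per-subject parameter table with the clinical table and runs,
#' per analyzed GMM parameter: the five-group ANOVA (Bonferroni alpha =
#' 0.05/8) with post-hoc contrasts, and ROC analyses for control-vs-MS and
#' RRMS-vs-progressive. Over MS subjects it fits the Z-scored regressions
#' of every biomarker on PDDS, reduces neuroperformance and
#' quality-of-life panels to first-principal-component composites (and
#' regresses each biomarker on them), and fits the LASSO disability model
#' with a 90/10 hold-out. Complete cases are used per analysis and counts
#' are reported.
#'
#' @param paramTable tidy per-subject parameter table (as stacked from
#'   \code{processSubject()$row}); one variant is selected
#' @param clinical clinical table with subject_id, group, pdds and optional
#'   npt_*/qol_* and atrophy columns
#' @param config a \code{\link{pipelineConfig}} (seed feeds the LASSO)
#' @param variant which GMM variant feeds the battery
#' @param outputDir optional directory for CSV/JSON result files
#' @return list with \code{anova}, \code{contrasts}, \code{roc},
#'   \code{regressions}, \code{pca}, \code{lasso}, \code{table}
#' @export
runStats <- function(paramTable, clinical, config = pipelineConfig(),
                     variant = "lesions_excluded", outputDir = NULL) {
  .checkColumns(paramTable, c("subject_id", "variant", .GMM_PARAMS))
  .checkColumns(clinical, c("subject_id", "group", "pdds"))
  pt <- paramTable[paramTable$variant == variant, ]
  d <- merge(pt, clinical, by = "subject_id")
  if (nrow(d) < 10L)
    stop("joined table has too few subjects (", nrow(d), ")")
  d$group <- factor(d$group, levels = intersect(.GROUPS, unique(d$group)))
  isMS <- d$group != "control"

  anovaRes <- lapply(setNames(.GMM_PARAMS, .GMM_PARAMS),
                     function(p) groupAnova(d, p))
  contrastRes <- lapply(setNames(.GMM_PARAMS, .GMM_PARAMS), function(p)
    suppressWarnings(posthocContrasts(d, p)))

  rocTab <- do.call(rbind, lapply(.GMM_PARAMS, function(p) {
    cvm <- rocAnalysis(d[[p]], isMS)
    out <- data.frame(parameter = p, comparison = "control_vs_MS",
                      auc = cvm$auc, sensitivity = cvm$sensitivity,
                      specificity = cvm$specificity)
    if (all(c("RRMS") %in% levels(d$group)) &&
        any(d$group %in% c("SPMS", "PPMS", "PRMS"))) {
      sel <- d$group != "control"
      rvp <- rocAnalysis(d[[p]][sel],
                         d$group[sel] %in% c("SPMS", "PPMS", "PRMS"))
      out <- rbind(out, data.frame(parameter = p,
                                   comparison = "RRMS_vs_progressive",
                                   auc = rvp$auc,
                                   sensitivity = rvp$sensitivity,
                                   specificity = rvp$specificity))
    }
    out
  }))

  biom <- c(.GMM_PARAMS, "lesion_volume", "lesion_intensity",
            intersect(c("bpf", "gmf", "wmf", "thalamic_volume"), names(d)))
  dm <- d[isMS, ]
  regTab <- do.call(rbind, lapply(biom, function(b) {
    r <- tryCatch(zscoreRegression(dm, b), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(biomarker = b, beta = r$beta, se = r$se, t = r$t, p = r$p,
               n = r$n)
  }))

  pcaRes <- list()
  for (panel in c("npt", "qol")) {
    cols <- grep(paste0("^", panel, "_"), names(dm), value = TRUE)
    if (length(cols) >= 2L) {
      cc <- complete.cases(dm[, cols])
      comp <- pcaComposite(dm[cc, cols])
      dcomp <- cbind(dm[cc, ], composite = comp$pc1)
      assoc <- do.call(rbind, lapply(biom, function(b) {
        r <- tryCatch(zscoreRegression(dcomp, b, outcome = "composite"),
                      error = function(e) NULL)
        if (is.null(r)) return(NULL)
        data.frame(biomarker = b, t = r$t, p = r$p, n = r$n)
      }))
      pcaRes[[panel]] <- list(varianceExplained = comp$varianceExplained,
                              loadings = comp$loadings,
                              associations = assoc)
    }
  }

  lassoFeat <- intersect(c(.GMM_PARAMS, "lesion_volume", "lesion_intensity",
                           "bpf", "gmf", "wmf", "thalamic_volume"),
                         names(dm))
  lassoRes <- tryCatch(
    lassoDisabilityModel(dm, lassoFeat, seed = config$seed),
    error = function(e) {
      warning("LASSO analysis skipped: ", conditionMessage(e))
      NULL
    })

  res <- list(anova = anovaRes, contrasts = contrastRes, roc = rocTab,
              regressions = regTab, pca = pcaRes, lasso = lassoRes,
              table = d)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(rocTab, file.path(outputDir, "roc.csv"), row.names = FALSE)
    if (!is.null(regTab))
      write.csv(regTab, file.path(outputDir, "regressions.csv"),
                row.names = FALSE)
    an <- data.frame(parameter = names(anovaRes),
                     F = vapply(anovaRes, `[[`, numeric(1), "F"),
                     p = vapply(anovaRes, `[[`, numeric(1), "p"),
                     significant = vapply(anovaRes, `[[`, logical(1),
                                          "significant"))
    write.csv(an, file.path(outputDir, "anova.csv"), row.names = FALSE)
    stars <- lapply(contrastRes, `[[`, "stars")
    writeLines(unlist(lapply(names(stars), function(p)
      c(p, utils::capture.output(print(stars[[p]], quote = FALSE)), ""))),
      file.path(outputDir, "contrast_matrices.txt"))
    if (!is.null(lassoRes))
      jsonlite::write_json(
        list(selected = as.list(lassoRes$selected),
             lambda = lassoRes$lambda, holdout_r2 = lassoRes$holdoutR2,
             n_train = lassoRes$nTrain, n_test = lassoRes$nTest),
        file.path(outputDir, "lasso.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
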