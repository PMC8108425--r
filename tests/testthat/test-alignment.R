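test_that("affine transforms compose, invert and serialize", {
  t1 <- intensityAffine(matrix(c(1.2, 0.1, -0.05, 0.9), 2, 2), c(30, -20))
  t2 <- invertAffine(t1)
  comp <- composeAffine(t2, t1)
  expect_equal(comp@linear, diag(2), tolerance = 1e-12)
  expect_equal(comp@offset, c(0, 0), tolerance = 1e-10)
  expect_error(intensityAffine(matrix(c(1, 0, 0, -1), 2, 2)), "det")

  path <- withr::local_tempfile(fileext = ".json")
  writeIntensityAffine(t1, path)
  rt <- readIntensityAffine(path)
  expect_equal(rt@linear, t1@linear)
  expect_equal(rt@offset, t1@offset)
})

test_that("self-registration returns the exact identity", {
  atlas <- testAtlas()
  subject <- initialize(referenceHistogram(atlas), nTotal = 1)
  res <- registerHistogram(subject, atlas)
  expect_true(res@converged)
  expect_lt(max(abs(alignTransform(res)@linear - diag(2))), 1e-6)
  expect_lt(max(abs(alignTransform(res)@offset)), 1e-6)
  expect_lt(alignError(res), 1e-12)
})

test_that("alignment error is zero at identity and bounded for disjoint mass", {
  cnt1 <- matrix(0, 64, 64); cnt1[3, 3] <- 5; cnt1[4, 3] <- 5
  cnt2 <- matrix(0, 64, 64); cnt2[50, 50] <- 2; cnt2[51, 50] <- 2
  h1 <- histFromCounts(cnt1)
  atlas1 <- atlasAround(histFromCounts(cnt1))
  expect_equal(alignmentError(h1, atlas1, intensityAffine(), smoothSigma = 0),
               0)
  # disjoint support: SSD of sqrt-masses is the sum of both total masses = 2
  atlas2 <- atlasAround(histFromCounts(cnt2))
  expect_equal(alignmentError(h1, atlas2, intensityAffine(), smoothSigma = 0),
               2)
  # degenerate single-bin histogram is refused
  single <- histFromCounts({m <- matrix(0, 64, 64); m[9, 9] <- 3; m})
  expect_error(registerHistogram(single, atlas2), "degenerate")
})

test_that("the optimum dominates every multi-start and the identity", {
  atlas <- testAtlas()
  ph <- generatePhantom(phantomSpec(
    seed = 31, scannerEffect = intensityAffine(diag(c(1.15, 0.88)),
                                               c(25, -15))))
  h <- buildBivariateHistogram(extractPairedIntensities(ph$pair),
                               binning(atlas))
  res <- registerHistogram(h, atlas)
  expect_lte(alignError(res), alignmentError(h, atlas, intensityAffine()))
  for (s in list(c(1.1, 1), c(0.9, 1), c(1, 1.1), c(1, 0.9)))
    expect_lte(alignError(res),
               alignmentError(h, atlas, intensityAffine(diag(s))))
})

test_that("non-affine gamma distortion raises alignment error above affine", {
  atlas <- testAtlas()
  errFor <- function(spec) {
    ph <- generatePhantom(spec)
    h <- buildBivariateHistogram(extractPairedIntensities(ph$pair),
                                 binning(atlas))
    alignError(registerHistogram(h, atlas))
  }
  clean <- vapply(6:8, function(i) errFor(phantomSpec(seed = i)), numeric(1))
  warped <- vapply(6:8, function(i)
    errFor(phantomSpec(seed = i, gammaDistortion = 1.6)), numeric(1))
  # every affinely-reachable subject aligns better than every gamma-warped
  # one, so a separating QC threshold exists
  expect_lt(max(clean), min(warped))
  thr <- (max(clean) + min(warped)) / 2
  results <- lapply(c(clean, warped), alignmentResultWithError)
  names(results) <- c(paste0("clean", 1:3), paste0("gamma", 1:3))
  gate <- qcGate(results, threshold = thr)
  expect_setequal(gate$kept, paste0("clean", 1:3))
  expect_setequal(gate$excluded, paste0("gamma", 1:3))
})

test_that("the automatic QC threshold excludes gross outliers only", {
  res <- lapply(c(a = 0.1, b = 0.1, c = 0.1, d = 9.0),
                alignmentResultWithError)
  gate <- qcGate(res, threshold = "auto")
  expect_setequal(gate$kept, c("a", "b", "c"))
  expect_equal(gate$excluded, "d")

  all_in <- qcGate(res, threshold = 10)
  expect_length(all_in$excluded, 0)
  none_in <- qcGate(res, threshold = 0)
  expect_length(none_in$kept, 0)

  plot <- withr::local_tempfile(fileext = ".pdf")
  qcGate(res, threshold = "auto", plotFile = plot)
  expect_true(file.size(plot) > 0)
})

test_that("voxelwise transform application matches its analytic effect", {
  ph <- generatePhantom(phantomSpec(shape = c(20, 20, 20), seed = 5))
  pair <- ph$pair
  idm <- applyIntensityTransform(pair, intensityAffine())
  expect_equal(idm@t1w[pair@brainMask != 0], pair@t1w[pair@brainMask != 0])
  expect_true(idm@standardized)

  dbl <- applyIntensityTransform(pair, intensityAffine(2 * diag(2)))
  inm <- pair@brainMask != 0
  expect_equal(dbl@t1w[inm], 2 * pair@t1w[inm])
  expect_equal(dbl@flair[inm], 2 * pair@flair[inm])
  expect_true(all(dbl@t1w[!inm] == 0))
  expect_identical(dbl@brainMask, pair@brainMask)
})

test_that("standardized images re-histogram close to the registered optimum", {
  atlas <- testAtlas()
  ph <- generatePhantom(phantomSpec(
    seed = 17, scannerEffect = intensityAffine(diag(c(1.2, 0.9)),
                                               c(30, -20))))
  h <- buildBivariateHistogram(extractPairedIntensities(ph$pair),
                               binning(atlas))
  res <- registerHistogram(h, atlas)
  std <- applyIntensityTransform(ph$pair, alignTransform(res))
  h2 <- buildBivariateHistogram(extractPairedIntensities(std),
                                binning(atlas))
  e2 <- alignmentError(h2, atlas, intensityAffine())
  expect_lte(e2, 1.05 * alignError(res) + 1e-8)
})

test_that("registration composes consistently across references", {
  # register X to an intermediate subject's histogram, then that subject to
  # the atlas; the composed transform should align X nearly as well as
  # direct registration
  atlas <- testAtlas()
  phX <- generatePhantom(phantomSpec(
    seed = 23, scannerEffect = intensityAffine(diag(c(1.15, 0.9)),
                                               c(20, -10))))
  phY <- generatePhantom(phantomSpec(
    seed = 24, scannerEffect = intensityAffine(diag(c(0.95, 1.05)),
                                               c(-10, 15))))
  hX <- buildBivariateHistogram(extractPairedIntensities(phX$pair),
                                binning(atlas))
  hY <- buildBivariateHistogram(extractPairedIntensities(phY$pair),
                                binning(atlas))
  atlasY <- atlasAround(hY)
  tXY <- alignTransform(registerHistogram(hX, atlasY))
  tYZ <- alignTransform(registerHistogram(hY, atlas))
  tDirect <- registerHistogram(hX, atlas)
  eComposed <- alignmentError(hX, atlas, composeAffine(tYZ, tXY))
  expect_lte(eComposed, 1.10 * alignError(tDirect) + 1e-6)
})
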