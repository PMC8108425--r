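pairedVals <- function(t1, flair) {
  new("PairedIntensities", t1 = as.numeric(t1), flair = as.numeric(flair),
      voxelIdx = seq_along(t1), nExcluded = 0L)
}

test_that("histogram conserves counts and clips out-of-range values", {
  spec <- binningSpec(64, 64, c(0, 1), c(0, 1))
  v <- pairedVals(rep(0.5, 4), rep(0.25, 4))
  h <- buildBivariateHistogram(v, spec, minVoxels = 1L)
  expect_equal(sum(histCounts(h)), 4)
  expect_equal(sum(histCounts(h) == 4), 1)   # one bin holds everything
  expect_equal(sum(histCounts(h) > 0), 1)

  # values beyond the range land in boundary bins, none are lost
  set.seed(1)
  v2 <- pairedVals(runif(5000, -1, 2), runif(5000, -1, 2))
  h2 <- buildBivariateHistogram(v2, spec)
  expect_equal(sum(histCounts(h2)), 5000)
  expect_gt(histCounts(h2)[1, 1], 0)
  expect_gt(histCounts(h2)[64, 64], 0)

  expect_error(buildBivariateHistogram(pairedVals(1, 1), spec),
               "too few voxels")
})

test_that("uniform sampling fills bins at the multinomial rate", {
  spec <- binningSpec(64, 64, c(0, 1), c(0, 1))
  set.seed(7)
  n <- 1e6
  h <- buildBivariateHistogram(pairedVals(runif(n), runif(n)), spec)
  mu <- n / (64 * 64)
  # every bin count within 5 sigma of its Poisson expectation
  expect_true(all(abs(histCounts(h) - mu) <= 5 * sqrt(mu)))
})

test_that("marginals conserve mass and sit on the right axis", {
  cnt <- matrix(0, 64, 64); cnt[5, 9] <- 7
  h <- histFromCounts(cnt)
  mt <- marginalizeHistogram(h, "t1")
  mf <- marginalizeHistogram(h, "flair")
  expect_equal(mt$counts[5], 7)
  expect_equal(mf$counts[9], 7)
  expect_equal(sum(mt$counts), sum(histCounts(h)))

  ph <- generatePhantom(phantomSpec(seed = 21))
  hp <- buildBivariateHistogram(extractPairedIntensities(ph$pair),
                                binning(testAtlas()))
  expect_equal(sum(marginalizeHistogram(hp, "flair")$counts), nVoxels(hp))
})

test_that("control-like marginals peak near the normative loci", {
  ph <- generatePhantom(phantomSpec(seed = 21))
  h <- buildBivariateHistogram(extractPairedIntensities(ph$pair),
                               binning(testAtlas()))
  peakNear <- function(m, locus) {
    sel <- abs(m$mids - locus) <= 60
    flank <- (m$mids > locus + 120 & m$mids < locus + 250) |
      (m$mids < locus - 120 & m$mids > locus - 250)
    max(m$counts[sel]) > max(m$counts[flank])
  }
  mt <- marginalizeHistogram(h, "t1")
  mf <- marginalizeHistogram(h, "flair")
  expect_true(peakNear(mt, 200))   # CSF
  expect_true(peakNear(mt, 600))   # GM
  expect_true(peakNear(mt, 1000))  # WM
  expect_true(peakNear(mf, 200))   # CSF
  expect_true(peakNear(mf, 700))   # WM
  expect_true(peakNear(mf, 1100))  # GM
})

test_that("reference atlas is an order-invariant, scale-invariant mean", {
  hs <- lapply(1:3, function(i)
    buildBivariateHistogram(
      extractPairedIntensities(generatePhantom(phantomSpec(seed = i))$pair),
      binning(testAtlas())))

  # two identical inputs: reference equals either, normalized
  a2 <- buildReferenceAtlas(list(hs[[1]], hs[[1]]))
  expect_equal(histCounts(referenceHistogram(a2)),
               histCounts(normalizeHistogram(hs[[1]])))

  aFwd <- buildReferenceAtlas(hs)
  aRev <- buildReferenceAtlas(rev(hs))
  expect_equal(histCounts(referenceHistogram(aFwd)),
               histCounts(referenceHistogram(aRev)))
  expect_equal(classCentroids(aFwd), classCentroids(aRev))

  # doubling every control's voxel count changes nothing after normalization
  doubled <- lapply(hs, function(h)
    initialize(h, counts = histCounts(h) * 2, nTotal = nVoxels(h) * 2))
  aDbl <- buildReferenceAtlas(doubled)
  expect_equal(histCounts(referenceHistogram(aDbl)),
               histCounts(referenceHistogram(aFwd)))

  # mismatched binning is refused
  other <- buildBivariateHistogram(
    extractPairedIntensities(generatePhantom(phantomSpec(seed = 9))$pair),
    binningSpec(128, 128, c(0, 2000), c(0, 2500)))
  expect_error(buildReferenceAtlas(list(hs[[1]], other)),
               "binning mismatch")
})

test_that("atlas centroids recover the generating class means", {
  atlas <- testAtlas()
  e <- binning(atlas)
  wT1 <- diff(e@rangeT1) / e@nBinsT1
  wFl <- diff(e@rangeFlair) / e@nBinsFlair
  cc <- classCentroids(atlas)
  expect_lt(abs(cc["GM", "t1"] - 600), 2 * wT1)
  expect_lt(abs(cc["WM", "t1"] - 1000), 2 * wT1)
  expect_lt(abs(cc["GM", "flair"] - 1100), 2 * wFl)
  expect_lt(abs(cc["WM", "flair"] - 700), 2 * wFl)
  # lesion locus is placed from the GM/WM geometry
  expect_equal(cc["LESION", "t1"], mean(cc[c("GM", "WM"), "t1"]))
  expect_gt(cc["LESION", "flair"], cc["GM", "flair"])
})

test_that("a pathological control set trips the ordering check", {
  # swap the GM and WM T1 means: no assignment of modes can satisfy both
  # the T1 and the FLAIR ordering constraints
  bad <- lapply(1:2, function(i) generatePhantom(phantomSpec(
    seed = i, classMeans = list(t1 = c(CSF = 200, GM = 1000, WM = 600),
                                flair = c(CSF = 200, WM = 700,
                                          GM = 1100))))$pair)
  vals <- lapply(bad, extractPairedIntensities)
  spec <- robustBinning(vals)
  hs <- lapply(vals, buildBivariateHistogram, spec = spec)
  expect_error(buildReferenceAtlas(hs, binning = spec),
               "ordering violation")
})

test_that("atlas archives round-trip through JSON", {
  atlas <- testAtlas()
  path <- withr::local_tempfile(fileext = ".json")
  writeAtlas(atlas, path)
  rt <- readAtlas(path)
  expect_equal(classCentroids(rt), classCentroids(atlas))
  expect_equal(histCounts(referenceHistogram(rt)),
               histCounts(referenceHistogram(atlas)))
  expect_equal(binning(rt)@rangeT1, binning(atlas)@rangeT1)
  expect_equal(rt@nControls, atlas@nControls)
})
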