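# Shared fixtures, built once per test run. Everything is generated in code
# from seeded phantom specs; no data files.

.fixtures <- new.env()

# normative atlas from five clean control phantoms on the default binning
testAtlas <- function() {
  if (is.null(.fixtures$atlas)) {
    ctrl <- lapply(1:5, function(i) generatePhantom(phantomSpec(seed = i))$pair)
    .fixtures$atlas <- buildAtlas(ctrl)
  }
  .fixtures$atlas
}

# phantoms are generated in scanner units; when the scanner effect is the
# identity they are already on the atlas scale and can skip registration
asStandardized <- function(pair) {
  pair@standardized <- TRUE
  pair
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# minimal valid atlas around an arbitrary reference histogram (for
# functional-value tests that need full control of the reference)
atlasAround <- function(refHist) {
  cc <- matrix(c(200, 600, 1000, 800, 200, 1100, 700, 1700), 4, 2,
               dimnames = list(c("CSF", "GM", "WM", "LESION"),
                               c("t1", "flair")))
  spec <- binningSpec(nrow(refHist@counts), ncol(refHist@counts),
                      range(refHist@edgesT1), range(refHist@edgesFlair))
  new("ReferenceAtlas", reference = normalizeHistogram(refHist),
      classCentroids = cc, nControls = 1L, binning = spec)
}

# uniform-edge raw histogram from a counts matrix
histFromCounts <- function(counts, rangeT1 = c(0, 2000),
                           rangeFlair = c(0, 2000)) {
  new("BivariateHistogram", counts = counts,
      edgesT1 = seq(rangeT1[1], rangeT1[2], length.out = nrow(counts) + 1),
      edgesFlair = seq(rangeFlair[1], rangeFlair[2],
                       length.out = ncol(counts) + 1),
      nTotal = sum(counts), normalized = FALSE)
}

alignmentResultWithError <- function(e) {
  new("AlignmentResult", transform = intensityAffine(), error = e,
      converged = TRUE, nIterations = 0L, qcPass = NA, qcThreshold = Inf)
}
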