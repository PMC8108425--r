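test_that("a single Gaussian is recovered at maximum-likelihood precision", {
  set.seed(11)
  n <- 5000
  x <- rnorm(n, 850, 40)
  fit <- fitUnivariateGMM(x, list(mu = 800, sigma = 60, weight = 1))
  comp <- fit$components
  expect_equal(comp$mu, mean(x), tolerance = 3 * 40 / sqrt(n) / mean(x))
  expect_lt(abs(comp$sigma - sd(x) * sqrt((n - 1) / n)),
            3 * 40 / sqrt(2 * n))
  expect_equal(comp$weight, 1)
})

test_that("a separated three-component mixture is recovered within tolerance", {
  set.seed(12)
  n <- 1e5
  mu0 <- c(CSF = 10, GM = 14, WM = 18)   # >= 4 sigma apart
  grp <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.4, 0.4))
  x <- rnorm(n, mu0[grp], 1)
  fit <- fitUnivariateGMM(x, list(mu = mu0, sigma = rep(1, 3),
                                  weight = c(0.2, 0.4, 0.4)))
  comp <- fit$components
  expect_true(fit$converged)
  expect_true(all(abs(comp$mu - mu0) / mu0 < 0.01))
  expect_true(all(abs(comp$sigma - 1) < 0.03))
  expect_equal(rownames(comp), c("CSF", "GM", "WM"))
  expect_equal(sum(comp$weight), 1, tolerance = 1e-9)
})

test_that("the EM log-likelihood never decreases", {
  set.seed(13)
  x <- c(rnorm(3000, 5), rnorm(3000, 9, 2))
  fit <- fitUnivariateGMM(x, list(mu = c(4, 10), sigma = c(2, 2),
                                  weight = c(0.5, 0.5)))
  expect_true(all(diff(fit$llTrace) >= -1e-6))
  # and with hard assignments (semi-supervised) as well
  ha <- integer(length(x)); ha[x > 12] <- 2L
  fit2 <- fitUnivariateGMM(x, list(mu = c(4, 10), sigma = c(2, 2),
                                   weight = c(0.5, 0.5)), hardAssign = ha)
  expect_true(all(diff(fit2$llTrace) >= -1e-6))
})

test_that("coincident components are flagged rather than silently returned", {
  set.seed(14)
  x <- rnorm(2000, 7, 1)
  res <- tryCatch(
    fitUnivariateGMM(x, list(mu = c(5, 9), sigma = c(1, 1),
                             weight = c(0.5, 0.5)), maxIter = 2000L),
    warning = function(w) w, error = function(e) e)
  if (inherits(res, "condition")) {
    expect_match(conditionMessage(res), "merged|degenerate|converge")
  } else {
    # identifiability failure: the two components overlap heavily
    cmp <- res$components
    expect_lt(diff(cmp$mu), 1.5 * sum(cmp$sigma))
  }
})

test_that("binned and voxel-sample EM paths agree closely", {
  set.seed(15)
  x <- c(rnorm(20000, 200, 50), rnorm(40000, 700, 55), rnorm(40000, 1100, 60))
  init <- list(mu = c(CSF = 200, WM = 700, GM = 1100),
               sigma = rep(50, 3), weight = c(0.2, 0.4, 0.4))
  fs <- fitUnivariateGMM(x, init)
  edges <- seq(min(x) - 1e-9, max(x) + 1e-9, length.out = 257)
  cnt <- tabulate(findInterval(x, edges, all.inside = TRUE), nbins = 256)
  fb <- fitUnivariateGMM((head(edges, -1) + tail(edges, -1)) / 2, init,
                         weights = cnt)
  expect_true(all(abs(fb$components$mu - fs$components$mu) /
                    fs$components$mu < 0.005))
  expect_true(all(abs(fb$components$sigma - fs$components$sigma) /
                    fs$components$sigma < 0.005))
})

test_that("seeded EM agrees with an independent mixture fitter", {
  library(mclust)   # Mclust resolves helpers from its attached namespace
  set.seed(16)
  x <- c(rnorm(15000, 250, 45), rnorm(30000, 690, 50),
         rnorm(25000, 1080, 60))
  fit <- fitUnivariateGMM(x, list(mu = c(200, 700, 1100),
                                  sigma = rep(50, 3),
                                  weight = rep(1 / 3, 3)))
  mc <- mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_true(all(abs(sort(fit$components$mu) - sort(mc$parameters$mean)) /
                    sort(mc$parameters$mean) < 0.01))
  expect_true(all(abs(sort(fit$components$sigma) -
                        sort(sqrt(mc$parameters$variance$sigmasq))) /
                    sort(sqrt(mc$parameters$variance$sigmasq)) < 0.02))
})

test_that("subject parameters carry atlas-fixed identities and react to lesions", {
  atlas <- testAtlas()
  ph <- generatePhantom(phantomSpec(seed = 18, lesionCount = 15))
  pair <- asStandardized(ph$pair)
  labs <- classifyTissues(pair, atlas)
  spEx <- extractSubjectParameters(pair, excludeLesions(labs), atlas,
                                   "lesions_excluded")
  spIn <- extractSubjectParameters(pair, labs, atlas, "lesions_included")
  pEx <- analyzedParameters(spEx)
  pIn <- analyzedParameters(spIn)
  # recovered class parameters near the generating values
  expect_equal(unname(pEx["t1_wm_mu"]), 1000, tolerance = 0.02)
  expect_equal(unname(pEx["flair_gm_mu"]), 1100, tolerance = 0.02)
  expect_equal(unname(pEx["flair_wm_sigma"]), 50, tolerance = 0.05)
  # lesion exclusion reduces FLAIR WM sigma when lesions are present
  expect_gt(unname(pIn["flair_wm_sigma"]), unname(pEx["flair_wm_sigma"]))
  # fitting WM-labeled voxels alone agrees with the seeded mixture on mu
  wmT1 <- pair@t1w[tissueLabels(labs) == 3L]
  solo <- fitUnivariateGMM(wmT1, list(mu = 1000, sigma = 50, weight = 1))
  expect_equal(solo$components$mu, unname(pEx["t1_wm_mu"]),
               tolerance = 0.02)
})

test_that("MS-like phantoms shift the analyzed parameters as the disease does", {
  atlas <- testAtlas()
  ctrl <- generatePhantom(phantomSpec(seed = 19))
  ms <- generatePhantom(phantomSpec(
    seed = 19,
    classMeans = list(t1 = c(CSF = 200, GM = 615, WM = 960),
                      flair = c(CSF = 200, WM = 685, GM = 1080)),
    classSD = 58, lesionCount = 12, nawmFieldSD = 40))
  pFor <- function(ph, variant = "lesions_excluded") {
    pair <- asStandardized(ph$pair)
    labs <- suppressWarnings(classifyTissues(pair, atlas))
    lv <- if (variant == "lesions_excluded") excludeLesions(labs) else labs
    analyzedParameters(extractSubjectParameters(pair, lv, atlas, variant))
  }
  pc <- pFor(ctrl); pm <- pFor(ms)
  expect_lt(pm[["t1_wm_mu"]], pc[["t1_wm_mu"]])       # darker WM on T1
  expect_gt(pm[["t1_wm_sigma"]], pc[["t1_wm_sigma"]]) # wider WM on T1
  expect_gt(pm[["flair_wm_sigma"]], pc[["flair_wm_sigma"]])
})
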