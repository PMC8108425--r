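test_that("two-group ANOVA reproduces the squared t statistic", {
  set.seed(21)
  d <- data.frame(group = rep(c("control", "RRMS"), each = 15),
                  y = c(rnorm(15, 0), rnorm(15, 0.8)))
  a <- groupAnova(d, "y")
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)

  # zero within-group variance, different means: essentially p = 0
  d2 <- data.frame(group = rep(c("a", "b"), each = 5), y = rep(c(1, 2),
                                                               each = 5))
  a2 <- groupAnova(d2, "y")
  expect_true(a2$significant)
  expect_lt(a2$p, 1e-12)

  expect_error(groupAnova(data.frame(group = "a", y = 1), "y"),
               "at least 2 groups")
})

test_that("post-hoc contrasts are symmetric and star-binned", {
  set.seed(22)
  d <- data.frame(
    group = rep(c("control", "RRMS", "SPMS"), each = 30),
    y = c(rnorm(30, 0), rnorm(30, 3), rnorm(30, 3.1)))
  ct <- posthocContrasts(d, "y")
  expect_equal(ct$p, t(ct$p))
  expect_equal(ct$t["control", "RRMS"], -ct$t["RRMS", "control"])
  expect_equal(ct$stars["control", "RRMS"], "****")  # huge separation
  # matched groups: weak or no evidence
  expect_gt(ct$p["RRMS", "SPMS"], 0.001)
  # omnibus warning when nothing differs
  d0 <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                   y = rep(1:10, 3) + 0)
  expect_warning(posthocContrasts(d0, "y"), "not significant")
})

test_that("rank AUC equals exhaustive pair counting, ties included", {
  bruteAuc <- function(v, l) {
    cas <- v[l]; con <- v[!l]
    cmp <- outer(cas, con, `-`)
    (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(cas) * length(con))
  }
  set.seed(23)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    v <- sample(1:12, n, replace = TRUE)   # heavy ties
    l <- as.logical(rbinom(n, 1, 0.5))
    if (!any(l) || all(l)) next
    r <- rocAnalysis(v, l, direction = "greater")
    expect_equal(r$auc, bruteAuc(v, l), tolerance = 1e-12)
  }
})

test_that("ROC endpoints behave: perfect separation and the null", {
  r <- rocAnalysis(c(1, 2, 3, 11, 12, 13), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  set.seed(24)
  r0 <- rocAnalysis(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(r0$auc - 0.5), 0.04)
  expect_error(rocAnalysis(1:5, rep(TRUE, 5)), "both cases and controls")
  # direction auto orients AUC above one half
  rl <- rocAnalysis(c(10, 9, 8, 1, 2, 3), c(F, F, F, T, T, T))
  expect_equal(rl$direction, "less")
  expect_equal(rl$auc, 1)
})

test_that("rank AUC matches an independent ROC implementation", {
  set.seed(25)
  v <- c(rnorm(40, 0), rnorm(40, 1))
  l <- rep(c(FALSE, TRUE), each = 40)
  r <- rocAnalysis(v, l)
  pr <- pROC::roc(l, v, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("Z-scored regression matches the closed-form OLS solution", {
  set.seed(26)
  pdds <- sample(0:8, 20, replace = TRUE)
  bio <- 3 + 0.7 * pdds + rnorm(20, 0, 0.5)
  d <- data.frame(pdds = pdds, bio = bio)
  r <- zscoreRegression(d, "bio")
  z <- (bio - mean(bio)) / sd(bio)
  betaHat <- sum((pdds - mean(pdds)) * (z - mean(z))) /
    sum((pdds - mean(pdds))^2)
  expect_equal(r$beta, betaHat, tolerance = 1e-12)
  expect_equal(r$n, 20)

  # exact linear relation: beta is the SD-scaled slope and p is tiny
  d2 <- data.frame(pdds = rep(0:8, 3), bio = 5 - 2 * rep(0:8, 3))
  r2 <- zscoreRegression(d2, "bio")
  expect_equal(r2$beta, -2 / sd(d2$bio), tolerance = 1e-12)
  expect_lt(r2$p, 1e-12)
  expect_error(zscoreRegression(data.frame(pdds = 0:9, bio = 1), "bio"),
               "zero-variance")
})

test_that("the PCA composite has analytic variance shares", {
  x <- rnorm(30)
  perf <- cbind(a = x, b = 3 * x + 5)      # perfectly correlated
  expect_equal(pcaComposite(perf)$varianceExplained, 1)

  orth <- cbind(a = rep(c(1, 1, -1, -1), 5), b = rep(c(1, -1, 1, -1), 5))
  expect_equal(pcaComposite(orth)$varianceExplained, 0.5)

  # planted one-factor structure with loadings 0.9: first eigenvalue of the
  # equicorrelation matrix is (1 + 2 rho) / 3 with rho = 0.81
  set.seed(27)
  n <- 20000
  f <- rnorm(n)
  panel <- sapply(1:3, function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(n))
  ve <- pcaComposite(panel)$varianceExplained
  expect_equal(ve, (1 + 2 * 0.81) / 3, tolerance = 0.03)
  # sign convention: largest loading positive
  expect_gt(max(pcaComposite(panel)$loadings), 0)
  expect_error(pcaComposite(cbind(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("the LASSO model is seed-reproducible and finds the signal", {
  set.seed(28)
  n <- 300
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  d <- data.frame(X, pdds = 2 * X[, 1] + rnorm(n, 0, 0.8))
  r1 <- lassoDisabilityModel(d, paste0("f", 1:6), seed = 5)
  r2 <- lassoDisabilityModel(d, paste0("f", 1:6), seed = 5)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$holdoutR2, r2$holdoutR2)
  expect_true("f1" %in% names(r1$selected))
  expect_gt(r1$holdoutR2, 0.5)
  expect_error(lassoDisabilityModel(d[1:20, ], paste0("f", 1:6)),
               "at least 50")
})
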