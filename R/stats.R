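## run expr with a fixed RNG seed, restoring the caller's RNG state after
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

.checkColumns <- function(table, cols) {
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("subject table is missing required column(s): ",
         paste(missing, collapse = ", "))
}

#' One-way group ANOVA on a biomarker
#'
#' Fits a one-way ANOVA of the parameter on disease group. With eight GMM
#' parameters tested, the Bonferroni-corrected significance level defaults
#' to 0.05 / 8 = 0.00625.
#'
#' @param table data.frame with a \code{group} column and the parameter
#' @param parameter column name of the biomarker
#' @param alpha significance level (default 0.05/8)
#' @return list with \code{F}, \code{p}, \code{df}, \code{significant}
#' @export
groupAnova <- function(table, parameter, alpha = 0.05 / 8) {
  .checkColumns(table, c("group", parameter))
  d <- table[complete.cases(table[, c("group", parameter)]), ]
  d$group <- droplevels(factor(d$group))
  tab <- table(d$group)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 groups with at least 2 subjects each")
  fit <- aov(stats::reformulate("group", parameter), data = d)
  an <- summary(fit)[[1]]
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       significant = an[["Pr(>F)"]][1] < alpha, alpha = alpha,
       n = nrow(d))
}

## star bins used in the contrast matrices:
## + p<0.05, * p<1e-2, ** p<1e-3, *** p<1e-4, **** p<1e-5
.starBin <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-5) return("****")
  if (p < 1e-4) return("***")
  if (p < 1e-3) return("**")
  if (p < 1e-2) return("*")
  if (p < 0.05) return("+")
  ""
}

#' Post-hoc pairwise group contrasts
#'
#' All pairwise mean contrasts between groups, as unadjusted t-contrasts
#' using the pooled ANOVA error variance, with the symmetric p-value matrix
#' and its star-bin coding (+ p<0.05 up to **** p<1e-5; empty =
#' nonsignificant). A warning (not a gate) is emitted when the omnibus
#' ANOVA is itself nonsignificant.
#'
#' @inheritParams groupAnova
#' @return list with matrices \code{t}, \code{p}, \code{stars} and the
#'   group \code{levels}
#' @export
posthocContrasts <- function(table, parameter, alpha = 0.05 / 8) {
  om <- groupAnova(table, parameter, alpha)
  if (!om$significant)
    warning("omnibus ANOVA for ", parameter, " is not significant (p = ",
            signif(om$p, 3), "); post-hoc contrasts are exploratory")
  d <- table[complete.cases(table[, c("group", parameter)]), ]
  d$group <- droplevels(factor(d$group))
  g <- levels(d$group)
  y <- d[[parameter]]
  means <- tapply(y, d$group, mean)
  ns <- tapply(y, d$group, length)
  ## pooled error variance from the one-way fit
  sse <- sum(tapply(y, d$group, function(v) sum((v - mean(v))^2)))
  dfe <- length(y) - length(g)
  mse <- sse / dfe
  k <- length(g)
  tm <- pm <- matrix(NA_real_, k, k, dimnames = list(g, g))
  sm <- matrix("", k, k, dimnames = list(g, g))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tij <- (means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    pij <- 2 * pt(-abs(tij), dfe)
    tm[i, j] <- tij; tm[j, i] <- -tij
    pm[i, j] <- pm[j, i] <- pij
    sm[i, j] <- sm[j, i] <- .starBin(pij)
  }
  list(t = tm, p = pm, stars = sm, levels = g, omnibus = om)
}

#' ROC analysis of a biomarker for a binary comparison
#'
#' AUC by the rank (Mann-Whitney) construction with mid-rank tie
#' correction; equivalent to the fraction of concordant (case, control)
#' pairs plus half the ties. The operating point is the Youden-optimal
#' threshold (maximizing sensitivity + specificity - 1), ties broken toward
#' higher specificity. Direction "auto" orients the comparison so AUC >=
#' 0.5.
#'
#' @param values biomarker values
#' @param labels logical (or 0/1) case indicator, TRUE = case
#' @param direction "auto", "greater" (cases higher) or "less"
#' @return list with \code{auc}, \code{sensitivity}, \code{specificity},
#'   \code{threshold}, \code{direction}, \code{n}
#' @export
rocAnalysis <- function(values, labels, direction = c("auto", "greater",
                                                      "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both cases and controls must be present")
  r <- rank(values)          # mid-ranks handle ties
  aucG <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (direction == "auto") direction <- if (aucG >= 0.5) "greater" else "less"
  auc <- if (direction == "greater") aucG else 1 - aucG
  ## candidate thresholds: midpoints between consecutive distinct values
  sv <- sort(unique(values))
  cand <- c(sv[1] - 1, (head(sv, -1) + tail(sv, -1)) / 2, sv[length(sv)] + 1)
  best <- NULL
  for (th in cand) {
    pos <- if (direction == "greater") values > th else values < th
    sens <- sum(pos & labels) / n1
    spec <- sum(!pos & !labels) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$specificity))
      best <- list(j = j, sensitivity = sens, specificity = spec,
                   threshold = th)
  }
  list(auc = auc, sensitivity = best$sensitivity,
       specificity = best$specificity, threshold = best$threshold,
       direction = direction, n = c(cases = n1, controls = n0))
}

#' Z-scored linear regression of a biomarker on disability
#'
#' The biomarker is standardized to zero mean and unit SD over the included
#' subjects, then regressed on the outcome (intercept + PDDS) by ordinary
#' least squares. Because every biomarker is on the same Z scale, the slope
#' beta is directly comparable across biomarkers. PDDS is treated as
#' numeric, matching linear fits of the ordinal scale.
#'
#' @param table data.frame of subject records
#' @param biomarker biomarker column name
#' @param outcome outcome column name (default "pdds")
#' @param minN minimum complete cases (default 10)
#' @return list with \code{beta}, \code{se}, \code{t}, \code{p}, \code{n}
#' @export
zscoreRegression <- function(table, biomarker, outcome = "pdds",
                             minN = 10L) {
  .checkColumns(table, c(biomarker, outcome))
  d <- table[complete.cases(table[, c(biomarker, outcome)]), ]
  if (nrow(d) < minN)
    stop("need at least ", minN, " complete cases, have ", nrow(d))
  x <- d[[biomarker]]
  if (sd(x) == 0) stop("zero-variance biomarker: ", biomarker)
  z <- (x - mean(x)) / sd(x)
  fit <- lm(z ~ d[[outcome]])
  cf <- summary(fit)$coefficients
  list(beta = cf[2, 1], se = cf[2, 2], t = cf[2, 3], p = cf[2, 4],
       n = nrow(d))
}

#' First-principal-component composite score
#'
#' Columns are standardized, the first principal component is extracted,
#' and its sign is fixed so the largest-magnitude loading is positive
#' (making the composite orientation reproducible).
#'
#' @param scores numeric matrix, subjects x measures (>= 3 subjects,
#'   >= 2 measures)
#' @return list with \code{pc1} (subject scores), \code{loadings},
#'   \code{varianceExplained} in [0, 1]
#' @export
pcaComposite <- function(scores) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) >= 3L, ncol(scores) >= 2L)
  sds <- apply(scores, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(scores)[sds == 0],
                                       collapse = ", "))
  pc <- prcomp(scores, center = TRUE, scale. = TRUE)
  load1 <- pc$rotation[, 1]
  s <- sign(load1[which.max(abs(load1))])
  list(pc1 = as.numeric(pc$x[, 1]) * s, loadings = load1 * s,
       varianceExplained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' LASSO model of disability with hold-out validation
#'
#' L1-penalized linear regression of the outcome on the biomarker panel,
#' which zeroes weak or redundant predictors: of two highly correlated,
#' equally predictive variables, the one with less sampling error survives.
#' The model is trained on a random 90 percent of complete cases (features
#' Z-scored on the training split only), with the penalty chosen by 10-fold
#' cross-validation (minimum-MSE rule by default), and evaluated on the
#' held-out 10 percent as the squared correlation between predicted and
#' observed outcome. Fully reproducible given \code{seed}.
#'
#' @param table data.frame of subject records
#' @param features character vector of feature column names
#' @param outcome outcome column name (default "pdds")
#' @param holdoutFraction held-out fraction (default 0.10)
#' @param seed integer seed controlling the split and CV folds
#' @param rule "min" (lambda at minimum CV error) or "1se"
#' @param nfolds CV folds on the training split
#' @return list with \code{selected} (named nonzero coefficients, intercept
#'   excluded), \code{coefficients} (all), \code{lambda},
#'   \code{holdoutR2}, \code{nTrain}, \code{nTest}
#' @export
lassoDisabilityModel <- function(table, features, outcome = "pdds",
                                 holdoutFraction = 0.10, seed = 1,
                                 rule = c("min", "1se"), nfolds = 10L) {
  rule <- match.arg(rule)
  .checkColumns(table, c(features, outcome))
  d <- table[complete.cases(table[, c(features, outcome)]), ]
  if (nrow(d) < 50L)
    stop("need at least 50 complete cases for the LASSO analysis, have ",
         nrow(d))
  n <- nrow(d)
  .withSeed(seed, {
    test <- sample.int(n, size = max(1L, round(holdoutFraction * n)))
    train <- setdiff(seq_len(n), test)
    X <- as.matrix(d[, features])
    y <- d[[outcome]]
    mu <- colMeans(X[train, , drop = FALSE])
    sg <- apply(X[train, , drop = FALSE], 2, sd)
    if (any(sg == 0))
      stop("zero-variance feature(s) in training split: ",
           paste(features[sg == 0], collapse = ", "))
    Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
    foldid <- sample(rep_len(seq_len(nfolds), length(train)))
    cv <- glmnet::cv.glmnet(Xs[train, , drop = FALSE], y[train],
                            alpha = 1, foldid = foldid,
                            standardize = FALSE)
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    beta <- as.matrix(coef(cv, s = lambda))[, 1]
    pred <- as.numeric(predict(cv, newx = Xs[test, , drop = FALSE],
                               s = lambda))
    r2 <- if (length(test) >= 3L && sd(pred) > 0)
      cor(pred, y[test])^2 else NA_real_
    sel <- beta[-1][beta[-1] != 0]
    list(selected = sel, coefficients = beta, lambda = lambda,
         holdoutR2 = r2, nTrain = length(train), nTest = length(test))
  })
}
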