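# Stratified resampling, RFECV with the first-quartile rule, grid search,
# the repeated holdout protocol, ROC/AUC, transfer and report comparison.

test_that("stratified k-fold balances classes and is seed-deterministic", {
  y <- rep(c("PD", "healthy"), each = 30)
  fold <- stratifiedKFold(y, 5, seed = 1)
  for (f in 1:5) {
    expect_equal(sum(fold == f & y == "PD"), 6)
    expect_equal(sum(fold == f & y == "healthy"), 6)
  }
  y2 <- c(rep("PD", 7), rep("healthy", 5))
  fold2 <- stratifiedKFold(y2, 3, seed = 2)
  tab <- table(fold2, y2)
  for (cl in colnames(tab)) expect_lte(max(tab[, cl]) - min(tab[, cl]), 1)
  expect_identical(stratifiedKFold(y, 5, seed = 9), stratifiedKFold(y, 5, seed = 9))
  expect_error(stratifiedKFold(c("PD", "PD", "healthy"), 2, 1),
               class = "phonoPD_stratification_error")
})

test_that("stratified 75/25 splits give {7, 8} test subjects per class", {
  y <- rep(c(1, 0), each = 30)
  for (i in 1:6) {
    inTest <- phonoPD:::.stratifiedSplit(y, 0.25, seed = i, parity = i)
    expect_equal(sum(inTest), 15)
    expect_true(all(sort(c(sum(inTest & y == 1), sum(inTest & y == 0))) == c(7, 8)))
  }
  # the extra subject's class alternates with parity at fixed seed
  a <- phonoPD:::.stratifiedSplit(y, 0.25, seed = 5, parity = 0)
  b <- phonoPD:::.stratifiedSplit(y, 0.25, seed = 5, parity = 1)
  expect_equal(sum(a & y == 1), sum(b & y == 0))
})

test_that("the first-quartile rule matches a sort-and-interpolate oracle", {
  expect_equal(phonoPD:::.quartileCount(rep(7L, 100)), 7L)
  set.seed(61)
  for (r in 1:20) {
    counts <- sample.int(33, sample(c(10, 100), 1), replace = TRUE)
    expect_identical(phonoPD:::.quartileCount(counts), quartileRef(counts))
  }
  cnt <- c(rep(5L, 4), rep(20L, 96))
  expect_identical(phonoPD:::.quartileCount(cnt), quartileRef(cnt))
  expect_identical(phonoPD:::.quartileCount(c(1L, 1L, 1L)), 1L)
})

test_that("RFECV finds a strong informative feature among noise", {
  hits <- 0
  for (s in 1:5) {
    ft <- synthCohort(nPerClass = 30, nFeatures = 10, informative = 1,
                      effectSizes = 4, seed = 70 + s)
    sel <- rfecvSelect(ft, nIterations = 20, seed = s)
    hits <- hits + ("f01" %in% selectedFeatures(sel))
    expect_true(all(optimalCounts(sel) >= 1 & optimalCounts(sel) <= 10))
    expect_identical(selectedFeatures(sel),
                     featureRanking(sel)[seq_len(sel@finalCount)])
  }
  expect_gte(hits, 5)
  ftBad <- synthCohort(nPerClass = 5, nFeatures = 3, seed = 1)
  ftBad@data$label <- "PD"
  expect_error(rfecvSelect(ftBad, nIterations = 2, seed = 1),
               class = "phonoPD_selection_error")
})

test_that("RFECV is deterministic given the master seed", {
  ft <- synthCohort(nPerClass = 15, nFeatures = 6, informative = 1,
                    effectSizes = 2, seed = 3)
  s1 <- rfecvSelect(ft, nIterations = 5, seed = 11)
  s2 <- rfecvSelect(ft, nIterations = 5, seed = 11)
  expect_identical(optimalCounts(s1), optimalCounts(s2))
  expect_identical(featureRanking(s1), featureRanking(s2))
})

test_that("grid search returns single combinations unchanged and is deterministic", {
  ft <- synthCohort(nPerClass = 15, nFeatures = 4, informative = 1,
                    effectSizes = 3, seed = 4)
  one <- gridSearch(ft, "logistic", grid = list(lambda = 0.5), seed = 1)
  expect_equal(one$best$lambda, 0.5)
  g1 <- gridSearch(ft, "logistic", seed = 2)
  g2 <- gridSearch(ft, "logistic", seed = 2)
  expect_identical(g1$best, g2$best)
  expect_identical(g1$table$cv_accuracy, g2$table$cv_accuracy)
})

test_that("grid search prefers hyperparameters that separate separable data", {
  # strong single feature: heavy ridge shrinkage cannot reach CV accuracy 1
  ft <- synthCohort(nPerClass = 20, nFeatures = 2, informative = 1,
                    effectSizes = 8, seed = 5)
  gs <- gridSearch(ft, "logistic", grid = list(lambda = c(1e-3, 1e4)), seed = 3)
  expect_equal(gs$best$lambda, 1e-3)
  expect_equal(gs$accuracy, 1, tolerance = 0.05)
})

test_that("AUC equals the brute-force concordance count", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(62)
  for (r in 1:10) {
    n <- sample(20:60, 1)
    sc <- round(rnorm(n), 1)  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(rocAuc(sc, y)$auc, aucRef(sc, y), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:4, rep(1, 4)), class = "phonoPD_undefined_metric_error")
})

test_that("a perfectly separating feature yields perfect holdout metrics", {
  ft <- synthCohort(nPerClass = 15, nFeatures = 3, informative = 1,
                    effectSizes = 20, seed = 6)
  r <- evaluate(ft, family = "logistic", nIterations = 25, seed = 1)
  s <- metricSummary(r)
  expect_equal(s$mean[s$metric == "accuracy"], 1)
  expect_equal(s$mean[s$metric == "auc"], 1)
  expect_true(all(dim(iterationMetrics(r)) == c(25, 4)))
  b <- rocBand(r)
  expect_equal(nrow(b), 101)
  expect_true(all(b$tpr_mean >= 0 & b$tpr_mean <= 1))
})

test_that("no training statistic is computed from test rows", {
  Xtr <- matrix(c(1, 2, 3, 4), 4, 2)
  Xte <- matrix(c(100, 200), 1, 2)  # extreme test values must not leak
  colnames(Xtr) <- colnames(Xte) <- c("a", "b")
  sc <- phonoPD:::.scalePair(Xtr, Xte)
  expect_equal(colMeans(sc$train), c(a = 0, b = 0))
  expect_equal(unname(sc$test[1, "a"]), (100 - mean(Xtr[, "a"])) / sd(Xtr[, "a"]))
  # missing values impute to the training mean (0 after scaling)
  Xtr2 <- Xtr; Xtr2[1, 1] <- NA
  sc2 <- phonoPD:::.scalePair(Xtr2, Xte)
  expect_equal(unname(sc2$train[1, 1]), 0)
})

test_that("every classifier family separates an easy cohort and ranks features", {
  ft <- synthCohort(nPerClass = 20, nFeatures = 4, informative = 1,
                    effectSizes = 6, seed = 7)
  X <- featureMatrix(ft)
  y <- as.numeric(subjectLabels(ft) == "PD")
  sc <- phonoPD:::.scalePair(X, X)
  for (fam in c("logistic", "random_forest", "perceptron",
                "passive_aggressive", "gradient_boosting", "svm")) {
    hyper <- if (fam == "svm") list(kernel = "linear") else list()
    model <- phonoPD:::.fitClassifier(fam, sc$train, y, hyper, seed = 1)
    expect_gte(phonoPD:::.scoreAccuracy(model, sc$train, y), 0.95)
    expect_identical(names(which.max(model$importance)), "f01")
  }
})

test_that("ridge logistic agrees with glm and glmnet cross-checks", {
  set.seed(63)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- rbinom(200, 1, plogis(X %*% c(1, -0.5, 0.2)))
  nearZero <- phonoPD:::.ridgeLogistic(X, y, lambda = 1e-8)
  ref <- unname(coef(glm.fit(cbind(1, X), y, family = binomial())))
  expect_equal(as.numeric(nearZero), ref, tolerance = 1e-4)
  skip_if_not_installed("glmnet")
  lam <- 2
  mine <- phonoPD:::.ridgeLogistic(X, y, lambda = lam)
  gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, standardize = FALSE,
                       lambda = lam / length(y), thresh = 1e-12)
  ref2 <- as.numeric(coef(gn))
  expect_equal(as.numeric(mine), ref2, tolerance = 0.05)
})

test_that("self-transfer in retrain mode reproduces the in-domain report", {
  ft <- synthCohort(nPerClass = 15, nFeatures = 4, informative = 1,
                    effectSizes = 2, seed = 8)
  r1 <- evaluate(ft, family = "logistic", nIterations = 10, seed = 3)
  r2 <- transferEvaluate(ft, ft, featureNames(ft), family = "logistic",
                         mode = "retrain", nIterations = 10, seed = 3)
  expect_identical(iterationMetrics(r1), iterationMetrics(r2))
})

test_that("frozen-model transfer degrades under covariate shift", {
  wins <- 0
  for (s in 1:6) {
    src <- synthCohort(nPerClass = 30, nFeatures = 6, informative = 1:2,
                       effectSizes = 1.5, seed = 80 + s)
    tgt <- applyCovariateShift(
      synthCohort(nPerClass = 30, nFeatures = 6, informative = 1:2,
                  effectSizes = 1.5, seed = 180 + s),
      shiftMean = 1, shiftScale = 2, features = c("f01", "f02"))
    inDom <- evaluate(src, family = "logistic", nIterations = 40, seed = s)
    trans <- transferEvaluate(src, tgt, featureNames(src), family = "logistic",
                              mode = "frozen", nIterations = 40, seed = s)
    wins <- wins + (mean(iterationMetrics(inDom)$accuracy) >
                      mean(iterationMetrics(trans)$accuracy))
  }
  expect_gte(wins, 5)
})

test_that("transfer refuses targets lacking the frozen features", {
  src <- synthCohort(nPerClass = 5, nFeatures = 3, seed = 9)
  tgt <- synthCohort(nPerClass = 5, nFeatures = 2, seed = 9)
  expect_error(transferEvaluate(src, tgt, c("f01", "f03"), family = "logistic"),
               class = "phonoPD_schema_error")
})

test_that("report comparison matches the textbook t statistic", {
  ft <- synthCohort(nPerClass = 15, nFeatures = 3, informative = 1,
                    effectSizes = 2, seed = 10)
  r <- evaluate(ft, family = "logistic", nIterations = 15, seed = 4)
  same <- compareReports(r, r)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  expect_false(any(same$significant))
  set.seed(64)
  for (rep in 1:5) {
    a <- rnorm(50, 0.9, 0.07); b <- rnorm(50, 0.85, 0.1)
    r1 <- r; r1@metrics$accuracy <- rep_len(a, nrow(r1@metrics))
    tt <- compareReports(r1, r)$t[1]
    expect_equal(tt, tRef(rep_len(a, nrow(r@metrics)), r@metrics$accuracy),
                 tolerance = 1e-9)
  }
  # strongly separated samples are flagged significant
  big <- r; big@metrics$accuracy <- rnorm(nrow(big@metrics), 0.9, 0.01)
  small <- r; small@metrics$accuracy <- rnorm(nrow(small@metrics), 0.7, 0.01)
  cmp <- compareReports(big, small)
  expect_lt(cmp$p[cmp$metric == "accuracy"], 0.001)
})

test_that("ROC band averaging is monotone and anchored at the corners", {
  ft <- synthCohort(nPerClass = 15, nFeatures = 3, informative = 1,
                    effectSizes = 1, seed = 11)
  r <- evaluate(ft, family = "logistic", nIterations = 20, seed = 5)
  b <- rocBand(r)
  expect_equal(b$fpr, seq(0, 1, by = 0.01))
  expect_true(all(diff(b$tpr_mean) >= -1e-12))
  expect_equal(b$tpr_mean[101], 1)
  p <- plotRocBand(r)
  expect_s3_class(p, "ggplot")
})
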