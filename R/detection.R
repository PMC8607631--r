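# The machine-learning engine: stratified resampling, recursive feature
# elimination with cross-validation and the first-quartile subset-size rule,
# grid-search tuning, the repeated stratified 75/25 holdout protocol with ROC
# averaging, cross-cohort transfer, and report comparison.

#' Stratified k-fold assignment
#'
#' Assigns records to `k` folds so that per-class counts across folds differ
#' by at most one; deterministic given `seed`.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return integer fold assignment (1..k) per record.
#' @export
stratifiedKFold <- function(labels, k, seed = 1L) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      .err("phonoPD_stratification_error",
           "class '%s' has %d members, fewer than k = %d", cl, length(idx), k)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split with largest-remainder per-class test counts;
# the extra subject's class alternates with iteration parity. Returns logical
# "in test set".
.stratifiedSplit <- function(labels, testFraction, seed, parity = 0L) {
  set.seed(as.integer(seed))
  classes <- sort(unique(labels))
  if (parity %% 2 == 1) classes <- rev(classes)
  nTest <- round(testFraction * length(labels))
  ideal <- vapply(classes, function(cl) testFraction * sum(labels == cl), 0)
  base <- floor(ideal)
  rem <- ideal - base
  extra <- nTest - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  inTest <- logical(length(labels))
  for (j in seq_along(classes)) {
    idx <- which(labels == classes[j])
    take <- max(1L, min(length(idx) - 1L, base[j]))
    inTest[sample(idx, take)] <- TRUE
  }
  inTest
}

# Standardize train/test matrices with training statistics only; missing
# values are imputed with the training mean (0 after standardization).
.scalePair <- function(Xtr, Xte) {
  ctr <- colMeans(Xtr, na.rm = TRUE)
  ctr[is.nan(ctr)] <- 0
  scl <- apply(Xtr, 2, stats::sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl <= 0] <- 1
  std <- function(M) {
    Z <- sweep(sweep(M, 2, ctr), 2, scl, "/")
    Z[is.na(Z)] <- 0
    Z
  }
  list(train = std(Xtr), test = std(Xte))
}

# First-quartile rule for the final subset size: linear-interpolation 25th
# percentile of the per-iteration optimal counts, rounded half up, >= 1.
.quartileCount <- function(counts) {
  q <- unname(stats::quantile(counts, 0.25, type = 7))
  max(1L, as.integer(floor(q + 0.5)))
}

#' Recursive feature elimination with cross-validation
#'
#' Repeats RFECV `nIterations` times with reshuffled stratified `k`-folds
#' (iteration `i` reseeds with `seed + i`). Within each fold the classifier
#' is fitted on the standardized training folds and features are removed one
#' at a time by weakest importance (absolute coefficient for linear families,
#' impurity/gain importance for tree families), scoring every subset size on
#' the held-out fold. Each iteration's optimal count is the size with the
#' best mean cross-validated accuracy (smallest size on ties); the final
#' count is the first quartile of the optimal counts (rounded half up,
#' floored at 1), and the selected features are the top-ranked ones by mean
#' elimination rank (ties alphabetical).
#'
#' @param ft a standardization-ready [FeatureTable-class] (raw features;
#'   scaling is fitted per training fold).
#' @param family classifier family (must expose a per-feature importance).
#' @param hyper named list of hyperparameters (defaults per family).
#' @param nIterations number of repeated CV iterations.
#' @param k folds per iteration.
#' @param seed master seed.
#' @return a [SelectionResult-class].
#' @export
rfecvSelect <- function(ft, family = "logistic", hyper = NULL,
                        nIterations = 100L, k = 5L, seed = 1L) {
  if (family == "svm") hyper <- utils::modifyList(list(kernel = "linear"), hyper %||% list())
  hyper <- hyper %||% list()
  X <- featureMatrix(ft)
  y <- as.numeric(subjectLabels(ft) == "PD")
  if (length(unique(y)) < 2) .err("phonoPD_selection_error", "labels are single-class")
  p <- ncol(X)
  if (p < 2) .err("phonoPD_selection_error", "need >= 2 features")
  fn <- colnames(X)
  t0 <- proc.time()[["elapsed"]]
  counts <- integer(nIterations)
  rankSum <- stats::setNames(numeric(p), fn)
  nRuns <- 0L
  for (iter in seq_len(nIterations)) {
    fold <- stratifiedKFold(y, k, seed = .iterSeed(seed, iter))
    accBySize <- matrix(0, k, p)
    for (f in seq_len(k)) {
      tr <- fold != f
      sc <- .scalePair(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      feats <- fn
      warm <- NULL  # coefficient warm start across elimination steps
      for (size in p:1) {
        model <- .fitClassifier(family, sc$train[, feats, drop = FALSE], y[tr],
                                hyper, seed = .iterSeed(seed, iter * 131L + f),
                                warm = warm)
        accBySize[f, size] <- .scoreAccuracy(model, sc$test[, feats, drop = FALSE], y[!tr])
        if (size > 1L) {
          worst <- feats[which.min(model$importance[feats])]
          rankSum[worst] <- rankSum[worst] + (p - size + 1L)
          if (!is.null(model$beta)) warm <- model$beta[c(TRUE, feats != worst)]
          feats <- setdiff(feats, worst)
        } else {
          rankSum[feats] <- rankSum[feats] + p
        }
      }
      nRuns <- nRuns + 1L
    }
    meanAcc <- colMeans(accBySize)
    counts[iter] <- which.max(meanAcc)  # ties -> smallest size
  }
  meanRank <- rankSum / nRuns
  ord <- order(-meanRank, fn)  # best kept longest; ties alphabetical
  ranking <- fn[ord]
  finalCount <- .quartileCount(counts)
  new("SelectionResult", optimalCounts = counts, ranking = ranking,
      finalCount = finalCount, selectedFeatures = ranking[seq_len(finalCount)],
      family = family, elapsedS = proc.time()[["elapsed"]] - t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grid-search hyperparameter tuning
#'
#' Exhaustive evaluation of every hyperparameter combination by stratified
#' `k`-fold cross-validated accuracy (scaling fitted per training fold);
#' returns the arg-max combination, ties broken by enumeration order (first
#' grid entry varies fastest). A classifier failure scores that combination
#' as 0 with a warning.
#'
#' @param ft a [FeatureTable-class] restricted to the features in use.
#' @param family classifier family.
#' @param grid named list of candidate values ([defaultHyperGrid()]).
#' @param k folds.
#' @param seed master seed.
#' @param features feature names to use (default: all in `ft`).
#' @return `list(best = <named list>, accuracy = <numeric>,
#'   table = <data.frame of all combinations>)`.
#' @export
gridSearch <- function(ft, family = "logistic", grid = defaultHyperGrid(family),
                       k = 5L, seed = 1L, features = featureNames(ft)) {
  if (length(grid) == 0) .err("phonoPD_spec_error", "empty hyperparameter grid")
  X <- featureMatrix(ft)[, features, drop = FALSE]
  y <- as.numeric(subjectLabels(ft) == "PD")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fold <- stratifiedKFold(y, k, seed = seed)
  acc <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    hyper <- as.list(combos[ci, , drop = FALSE])
    a <- tryCatch({
      vals <- vapply(seq_len(k), function(f) {
        tr <- fold != f
        sc <- .scalePair(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
        model <- .fitClassifier(family, sc$train, y[tr], hyper,
                                seed = .iterSeed(seed, ci * 17L + f))
        .scoreAccuracy(model, sc$test, y[!tr])
      }, 0)
      mean(vals)
    }, error = function(e) {
      warning(sprintf("combination %d failed (%s); scored 0", ci, conditionMessage(e)))
      0
    })
    acc[ci] <- a
  }
  best <- which.max(acc)  # first occurrence wins ties
  list(best = as.list(combos[best, , drop = FALSE]), accuracy = acc[best],
       table = cbind(combos, cv_accuracy = acc))
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with tied scores stepping
#' simultaneously; AUC by the trapezoidal rule (equivalent to the
#' Mann-Whitney concordance probability with ties counted 1/2).
#'
#' @param scores continuous classifier scores (larger = more PD-like).
#' @param labels class labels (`"PD"`/`"healthy"`, or 0/1 with 1 = PD).
#' @return `list(curve = data.frame(fpr, tpr), auc = numeric)`.
#' @export
rocAuc <- function(scores, labels) {
  y <- if (is.numeric(labels)) as.integer(labels == 1) else as.integer(labels == "PD")
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    .err("phonoPD_undefined_metric_error", "both classes required for ROC")
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]; ss <- scores[o]
  # collapse tied scores into simultaneous steps
  lastOfGroup <- c(diff(ss) != 0, TRUE)
  tp <- cumsum(ys)[lastOfGroup]
  fp <- cumsum(1 - ys)[lastOfGroup]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

.tprAtGrid <- function(curve, grid) {
  stats::approx(curve$fpr, curve$tpr, xout = grid, ties = max, rule = 2)$y
}

#' Repeated stratified holdout evaluation
#'
#' The classification protocol: `nIterations` random stratified
#' train/test splits (75/25 by default; per-class test counts by largest
#' remainder with the extra subject's class alternating by iteration
#' parity), scaler fitted on the training split only, missing values imputed
#' with training means, classifier fitted and scored on the test split.
#' Reports per-iteration accuracy, sensitivity, specificity (PD = positive
#' class) and AUC, and a vertically averaged ROC curve with a +/- 1 sd band
#' on a 101-point FPR grid.
#'
#' @param ft a raw (unscaled) [FeatureTable-class], one row per subject.
#' @param features feature names to use (e.g. from [rfecvSelect()]).
#' @param family classifier family.
#' @param hyper named list of hyperparameters.
#' @param nIterations number of holdout iterations.
#' @param testFraction held-out fraction.
#' @param seed master seed; iteration `i` derives its own seed from it.
#' @return an [EvaluationReport-class].
#' @export
evaluate <- function(ft, features = featureNames(ft), family = "logistic",
                     hyper = NULL, nIterations = 1000L, testFraction = 0.25,
                     seed = 1L) {
  if (inherits(features, "SelectionResult")) features <- selectedFeatures(features)
  hyper <- hyper %||% list()
  X <- featureMatrix(ft)[, features, drop = FALSE]
  y <- as.numeric(subjectLabels(ft) == "PD")
  if (sum(y == 1) < 4 || sum(y == 0) < 4)
    .err("phonoPD_spec_error", "need >= 4 subjects per class")
  grid <- seq(0, 1, by = 0.01)
  mets <- matrix(NA_real_, nIterations, 4,
                 dimnames = list(NULL, c("accuracy", "sensitivity", "specificity", "auc")))
  tprs <- matrix(NA_real_, nIterations, length(grid))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nIterations)) {
    si <- .iterSeed(seed, i)
    inTest <- .stratifiedSplit(y, testFraction, seed = si, parity = i)
    sc <- .scalePair(X[!inTest, , drop = FALSE], X[inTest, , drop = FALSE])
    model <- .fitClassifier(family, sc$train, y[!inTest], hyper, seed = si)
    scores <- model$predict(sc$test)
    yTest <- y[inTest]
    pred <- as.integer(scores > model$threshold)
    tp <- sum(pred == 1 & yTest == 1); tn <- sum(pred == 0 & yTest == 0)
    fp <- sum(pred == 1 & yTest == 0); fn <- sum(pred == 0 & yTest == 1)
    roc <- rocAuc(scores, yTest)
    mets[i, ] <- c((tp + tn) / length(yTest), tp / (tp + fn), tn / (tn + fp), roc$auc)
    tprs[i, ] <- .tprAtGrid(roc$curve, grid)
  }
  new("EvaluationReport",
      metrics = as.data.frame(mets),
      rocFpr = grid,
      rocTprMean = colMeans(tprs),
      rocTprSd = apply(tprs, 2, stats::sd),
      family = family,
      hyperparameters = hyper,
      timingsS = c(selection = NA_real_, grid_search = NA_real_,
                   classification = proc.time()[["elapsed"]] - t0))
}

#' Cross-cohort transfer evaluation
#'
#' Applies a feature subset and hyperparameters frozen from a source-cohort
#' experiment to a target cohort, with no re-selection and no re-tuning.
#' Two protocols are available: `"retrain"` (default) re-runs the holdout
#' protocol on the target cohort with the frozen feature set and
#' hyperparameters; `"frozen"` trains on stratified 75% subsamples of the
#' source cohort and scores stratified 25% subsamples of the target, so the
#' decision rule itself crosses cohorts and covariate shift between them is
#' felt directly.
#'
#' @param source the source [FeatureTable-class] (used by `"frozen"` mode).
#' @param target the target [FeatureTable-class].
#' @param features frozen feature names or a [SelectionResult-class].
#' @param family classifier family.
#' @param hyper frozen hyperparameters.
#' @param mode `"retrain"` or `"frozen"`.
#' @param nIterations,testFraction,seed as in [evaluate()].
#' @return an [EvaluationReport-class].
#' @export
transferEvaluate <- function(source, target, features, family = "logistic",
                             hyper = NULL, mode = c("retrain", "frozen"),
                             nIterations = 1000L, testFraction = 0.25, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(features, "SelectionResult")) features <- selectedFeatures(features)
  missingCols <- setdiff(setdiff(features, "sex"), names(tableData(target)))
  if (length(missingCols))
    .err("phonoPD_schema_error", "target lacks feature columns: %s",
         paste(missingCols, collapse = ", "))
  if (mode == "retrain") {
    return(evaluate(target, features, family, hyper, nIterations, testFraction, seed))
  }
  hyper <- hyper %||% list()
  Xs <- featureMatrix(source)[, features, drop = FALSE]
  ys <- as.numeric(subjectLabels(source) == "PD")
  Xt <- featureMatrix(target)[, features, drop = FALSE]
  yt <- as.numeric(subjectLabels(target) == "PD")
  grid <- seq(0, 1, by = 0.01)
  mets <- matrix(NA_real_, nIterations, 4,
                 dimnames = list(NULL, c("accuracy", "sensitivity", "specificity", "auc")))
  tprs <- matrix(NA_real_, nIterations, length(grid))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nIterations)) {
    si <- .iterSeed(seed, i)
    trSrc <- !.stratifiedSplit(ys, testFraction, seed = si, parity = i)
    teTgt <- .stratifiedSplit(yt, testFraction, seed = si + 1L, parity = i)
    sc <- .scalePair(Xs[trSrc, , drop = FALSE], Xt[teTgt, , drop = FALSE])
    model <- .fitClassifier(family, sc$train, ys[trSrc], hyper, seed = si)
    scores <- model$predict(sc$test)
    yTest <- yt[teTgt]
    pred <- as.integer(scores > model$threshold)
    tp <- sum(pred == 1 & yTest == 1); tn <- sum(pred == 0 & yTest == 0)
    fp <- sum(pred == 1 & yTest == 0); fn <- sum(pred == 0 & yTest == 1)
    roc <- rocAuc(scores, yTest)
    mets[i, ] <- c((tp + tn) / length(yTest), tp / (tp + fn), tn / (tn + fp), roc$auc)
    tprs[i, ] <- .tprAtGrid(roc$curve, grid)
  }
  new("EvaluationReport",
      metrics = as.data.frame(mets),
      rocFpr = grid, rocTprMean = colMeans(tprs), rocTprSd = apply(tprs, 2, stats::sd),
      family = family, hyperparameters = hyper,
      timingsS = c(selection = NA_real_, grid_search = NA_real_,
                   classification = proc.time()[["elapsed"]] - t0))
}

#' Compare two evaluation reports metric by metric
#'
#' Two-sample t-tests on the per-iteration metric samples (Student's
#' equal-variance by default, Welch optionally), flagging significance at
#' 0.05. Two identical zero-variance samples give `t = 0`, `p = 1` by
#' convention.
#'
#' @param r1,r2 [EvaluationReport-class] objects.
#' @param welch use the Welch (unequal-variance) variant.
#' @return data.frame with `metric`, `t`, `df`, `p`, `significant`.
#' @export
compareReports <- function(r1, r2, welch = FALSE) {
  out <- lapply(c("accuracy", "sensitivity", "specificity", "auc"), function(mn) {
    a <- iterationMetrics(r1)[[mn]]; b <- iterationMetrics(r2)[[mn]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        return(data.frame(metric = mn, t = 0, df = length(a) + length(b) - 2,
                          p = 1, significant = FALSE))
      }
      return(data.frame(metric = mn, t = Inf, df = length(a) + length(b) - 2,
                        p = 0, significant = TRUE))
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    data.frame(metric = mn, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < 0.05)
  })
  do.call(rbind, out)
}

#' Run the full detection pipeline on a cohort
#'
#' Feature selection (RFECV + first-quartile rule), grid-search tuning on
#' the selected subset, and the repeated stratified holdout evaluation, with
#' a run-time breakdown, mirroring the reference methodology end to end.
#'
#' @param ft a raw per-subject [FeatureTable-class].
#' @param family classifier family.
#' @param selectionIterations,evalIterations iteration counts for the
#'   selection and classification stages.
#' @param k folds for selection and tuning.
#' @param grid hyperparameter grid.
#' @param seed master seed.
#' @return `list(selection = SelectionResult, tuning = <gridSearch output>,
#'   report = EvaluationReport)`.
#' @export
runPipeline <- function(ft, family = "logistic", selectionIterations = 100L,
                        evalIterations = 1000L, k = 5L,
                        grid = defaultHyperGrid(family), seed = 1L) {
  sel <- rfecvSelect(ft, family, nIterations = selectionIterations, k = k, seed = seed)
  t0 <- proc.time()[["elapsed"]]
  tune <- gridSearch(ft, family, grid = grid, k = k, seed = seed,
                     features = selectedFeatures(sel))
  tGrid <- proc.time()[["elapsed"]] - t0
  rep <- evaluate(ft, selectedFeatures(sel), family, tune$best,
                  nIterations = evalIterations, seed = seed)
  rep@timingsS <- c(selection = sel@elapsedS, grid_search = tGrid,
                    classification = unname(rep@timingsS["classification"]))
  list(selection = sel, tuning = tune, report = rep)
}

#' Plot an averaged ROC curve with its +/- 1 sd band
#'
#' @param report an [EvaluationReport-class].
#' @return a ggplot object.
#' @export
plotRocBand <- function(report) {
  d <- rocBand(report)
  d$lo <- pmax(0, d$tpr_mean - d$tpr_sd)
  d$hi <- pmin(1, d$tpr_mean + d$tpr_sd)
  ggplot2::ggplot(d, ggplot2::aes(x = fpr, y = tpr_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "False-positive rate (1 - specificity)",
                  y = "True-positive rate (sensitivity)",
                  title = sprintf("Mean ROC (+/- 1 sd), %s", report@family)) +
    ggplot2::theme_minimal()
}
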