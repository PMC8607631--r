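# Uniform fit/score/importance interface over the six classifier families.
# Inputs are standardized numeric matrices; y is 1 for PD, 0 for healthy.
# Scores are continuous (probability for probabilistic families, signed
# decision value for margin families); the predicted class threshold is
# stored with the model.

.familyNames <- c("logistic", "random_forest", "perceptron",
                  "passive_aggressive", "gradient_boosting", "svm")

#' Default hyperparameter grids
#'
#' Small documented grids per classifier family for [gridSearch()]. Values
#' are enumerated with the first hyperparameter varying fastest; ties in CV
#' accuracy are broken by enumeration order.
#'
#' @param family one of `"logistic"`, `"random_forest"`, `"perceptron"`,
#'   `"passive_aggressive"`, `"gradient_boosting"`, `"svm"`, or `NULL` for
#'   the full list.
#' @return a named list of candidate-value vectors (or a list of such lists).
#' @export
defaultHyperGrid <- function(family = NULL) {
  grids <- list(
    logistic = list(lambda = c(0.01, 0.1, 1, 10)),
    random_forest = list(num_trees = c(100, 300)),
    perceptron = list(epochs = c(10, 30)),
    passive_aggressive = list(C = c(0.01, 0.1, 1)),
    gradient_boosting = list(max_depth = c(2, 3), eta = c(0.05, 0.1)),
    svm = list(kernel = c("linear", "radial"), cost = c(0.1, 1, 10))
  )
  if (is.null(family)) grids else grids[[match.arg(family, .familyNames)]]
}

.defaultHyper <- function(family) {
  switch(family,
    logistic = list(lambda = 1),
    random_forest = list(num_trees = 100),
    perceptron = list(epochs = 20),
    passive_aggressive = list(C = 1, epochs = 20),
    gradient_boosting = list(max_depth = 3, eta = 0.1, nrounds = 100),
    svm = list(kernel = "radial", cost = 1))
}

# Ridge-penalized logistic regression by IRLS. Penalty lambda/2 * ||beta||^2
# (intercept unpenalized). Written for the tight inner loop of recursive
# feature elimination; agreement with glm/glmnet is covered by tests.
.ridgeLogistic <- function(X, y, lambda = 1e-2, maxit = 30, tol = 1e-8,
                           beta0 = NULL) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- if (is.null(beta0) || length(beta0) != p) numeric(p) else beta0
  pen <- diag(c(0, rep(max(lambda, 1e-8), p - 1)), p)  # floor keeps H positive definite
  for (it in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-9)
    z <- eta + (y - mu) / w
    Xw <- X1 * w
    betaNew <- solve(crossprod(Xw, X1) + pen, crossprod(Xw, z))
    if (max(abs(betaNew - beta)) < tol) { beta <- betaNew; break }
    beta <- betaNew
  }
  as.vector(beta)
}

# Fit one classifier. Returns list(predict = function(X) scores,
# threshold, importance = named numeric or NULL, family).
.fitClassifier <- function(family, X, y, hyper = list(), seed = 1L, warm = NULL) {
  family <- match.arg(family, .familyNames)
  hyper <- utils::modifyList(.defaultHyper(family), hyper)
  fn <- colnames(X)
  if (family == "logistic") {
    beta <- .ridgeLogistic(X, y, lambda = hyper$lambda, beta0 = warm)
    imp <- abs(beta[-1]); names(imp) <- fn
    list(predict = function(Z) 1 / (1 + exp(-as.vector(cbind(1, Z) %*% beta))),
         threshold = 0.5, importance = imp, family = family, beta = beta)
  } else if (family == "random_forest") {
    df <- as.data.frame(X)
    df$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = hyper$num_trees, probability = TRUE,
                          importance = "impurity", seed = as.integer(seed),
                          num.threads = 1)
    imp <- fit$variable.importance[fn]
    imp[is.na(imp)] <- 0
    list(predict = function(Z) {
           stats::predict(fit, data = as.data.frame(Z),
                          num.threads = 1)$predictions[, "1"]
         },
         threshold = 0.5, importance = imp, family = family)
  } else if (family == "perceptron") {
    set.seed(as.integer(seed))
    ord <- unlist(lapply(seq_len(hyper$epochs),
                         function(e) sample.int(nrow(X)))) - 1L
    wb <- .perceptron_fit(X, ifelse(y == 1, 1, -1), ord, as.integer(hyper$epochs))
    imp <- abs(wb[-1]); names(imp) <- fn
    list(predict = function(Z) as.vector(cbind(1, Z) %*% wb),
         threshold = 0, importance = imp, family = family)
  } else if (family == "passive_aggressive") {
    set.seed(as.integer(seed))
    ord <- unlist(lapply(seq_len(hyper$epochs),
                         function(e) sample.int(nrow(X)))) - 1L
    wb <- .pa_fit(X, ifelse(y == 1, 1, -1), ord, as.integer(hyper$epochs),
                  as.numeric(hyper$C))
    imp <- abs(wb[-1]); names(imp) <- fn
    list(predict = function(Z) as.vector(cbind(1, Z) %*% wb),
         threshold = 0, importance = imp, family = family)
  } else if (family == "gradient_boosting") {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            max_depth = hyper$max_depth,
                                            eta = hyper$eta, nthread = 1,
                                            seed = as.integer(seed)),
                              data = dtrain, nrounds = hyper$nrounds, verbose = 0)
    impTab <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
    imp <- stats::setNames(rep(0, length(fn)), fn)
    if (!is.null(impTab) && nrow(impTab)) imp[impTab$Feature] <- impTab$Gain
    list(predict = function(Z) stats::predict(fit, xgboost::xgb.DMatrix(Z, nthread = 1)),
         threshold = 0.5, importance = imp, family = family)
  } else { # svm
    kern <- if (identical(hyper$kernel, "linear")) "linear" else "radial"
    gamma <- if (!is.null(hyper$gamma) && hyper$gamma > 0) hyper$gamma else 1 / ncol(X)
    fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = kern,
                      cost = hyper$cost, gamma = gamma, scale = FALSE)
    # orient decision values so larger = PD: the decision column is named
    # "A/B" with positive values favoring class A
    dv0 <- attr(stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
                "decision.values")
    flip <- if (startsWith(colnames(dv0)[1], "1")) 1 else -1
    imp <- NULL
    if (kern == "linear") {
      wvec <- as.vector(t(fit$coefs) %*% fit$SV) * flip
      imp <- abs(wvec); names(imp) <- fn
    }
    list(predict = function(Z) {
           dv <- attr(stats::predict(fit, Z, decision.values = TRUE),
                      "decision.values")
           as.vector(dv) * flip
         },
         threshold = 0, importance = imp, family = family)
  }
}

.scoreAccuracy <- function(model, X, y) {
  mean((model$predict(X) > model$threshold) == (y == 1))
}
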