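#' Classifier family specification
#'
#' The seven families under study, each behind one uniform fit/predict
#' contract.  `grid` lists candidate metaparameters; `scaling` says whether
#' features are z-scored (center/scale fit on the training rows only) before
#' fitting, which the distance- and margin-based families require.
#'
#' @param family one of `"DT"`, `"KNN"`, `"SVM_linear"`, `"SVM_RBF"`,
#'   `"ADA"`, `"RF"`, `"ANN"`.
#' @param grid named list of candidate metaparameter values; defaults from
#'   [default_grids()].
#' @param scaling logical; default `TRUE` for KNN/SVM/ANN, `FALSE` for the
#'   tree-based families.
#' @return a list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("DT", "KNN", "SVM_linear", "SVM_RBF",
                                       "ADA", "RF", "ANN"),
                            grid = NULL, scaling = NULL) {
  family <- match.arg(family)
  grid <- grid %||% default_grids()[[family]]
  stopifnot(is.list(grid), length(grid) >= 1L, all(lengths(grid) >= 1L))
  scaling <- scaling %||% (family %in% c("KNN", "SVM_linear", "SVM_RBF", "ANN"))
  structure(list(family = family, grid = grid, scaling = scaling),
            class = "classifier_spec")
}

#' Default metaparameter grids
#'
#' Wide search grids for the tunables of each family: tree depth for DT, the
#' neighbour count K for KNN, the soft margin C for the linear SVM, C and
#' the kernel width parameter gamma for the RBF SVM, depth and tree count
#' for the random forest, the number of boosted stumps for AdaBoost and the
#' hidden-layer size for the neural network.
#'
#' @return named list of grids, one per family.
#' @export
default_grids <- function() {
  list(DT  = list(maxdepth = 2:20),
       KNN = list(k = seq(1, 51, by = 2)),
       SVM_linear = list(cost = c(0.01, 0.1, 1, 10, 100)),
       SVM_RBF = list(cost = c(0.01, 0.1, 1, 10, 100),
                      gamma = 10^seq(-3, 1)),
       ADA = list(n_estimators = c(25, 50, 100, 200)),
       RF  = list(maxdepth = 4:16, num_trees = c(50, 100, 200)),
       ANN = list(size = c(4, 8, 16, 32, 64)))
}

#' Compact metaparameter grids for desk-scale runs
#'
#' Thinned versions of [default_grids()] covering the same ranges with far
#' fewer points; used by the bundled analysis scripts and tests so a full
#' 7-family by 6-feature-set experiment stays fast on one CPU.
#'
#' @return named list of grids, one per family.
#' @export
compact_grids <- function() {
  list(DT  = list(maxdepth = c(3, 6, 12)),
       KNN = list(k = c(5, 15, 31)),
       SVM_linear = list(cost = c(0.1, 1, 10)),
       SVM_RBF = list(cost = c(1, 10), gamma = c(0.01, 0.1, 1)),
       ADA = list(n_estimators = c(25, 50)),
       RF  = list(maxdepth = c(6, 12), num_trees = 100),
       ANN = list(size = c(8, 16)))
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(X, sc) {
  scale(X, center = sc$center, scale = sc$scale)
}

#' Fit one classifier under the uniform contract
#'
#' @param spec a [classifier_spec()].
#' @param X numeric matrix/data.frame of features (rows = segments).
#' @param y factor or character class labels (`"AF"`/`"SR"`).
#' @param params named list giving one value for each grid entry.
#' @param seed integer seed for the stochastic families (RF, ANN).
#' @return an object of class `af_classifier` with a [predict][predict.af_classifier]
#'   method returning `"AF"`/`"SR"` labels.
#' @export
fit_classifier <- function(spec, X, y, params, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(as.character(y), levels = c("SR", "AF"))
  stopifnot(!anyNA(y), nrow(X) == length(y))
  sc <- NULL
  if (spec$scaling) {
    sc <- scale_fit(X)
    X <- scale_apply(X, sc)
  }
  df <- data.frame(X)
  df$.y <- y
  model <- switch(
    spec$family,
    DT = rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = params$maxdepth, cp = 0, xval = 0,
                        minsplit = 4, minbucket = 2)),
    KNN = {
      # cap K below the training size, keeping it odd so binary votes
      # cannot tie
      k <- min(params$k, nrow(X) - 1L)
      if (k %% 2 == 0) k <- k - 1L
      list(train = X, cl = y, k = max(k, 1L))
    },
    SVM_linear = e1071::svm(X, y, kernel = "linear", cost = params$cost,
                            scale = FALSE),
    SVM_RBF = e1071::svm(X, y, kernel = "radial", cost = params$cost,
                         gamma = params$gamma, scale = FALSE),
    ADA = fit_adaboost(X, y, n_estimators = params$n_estimators),
    RF = ranger::ranger(.y ~ ., data = df, num.trees = params$num_trees,
                        max.depth = params$maxdepth, seed = seed,
                        num.threads = 1),
    ANN = with_local_seed(seed,
      nnet::nnet(.y ~ ., data = df, size = params$size, decay = 1e-4,
                 maxit = 200, trace = FALSE, MaxNWts = 5000)))
  structure(list(spec = spec, model = model, params = params,
                 scaler = sc, features = colnames(X)),
            class = "af_classifier")
}

#' Predict rhythm classes
#'
#' @param object an `af_classifier` from [fit_classifier()].
#' @param newdata feature matrix/data.frame with the training columns.
#' @param ... unused.
#' @return character vector of `"AF"`/`"SR"` labels.
#' @export
predict.af_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  if (!is.null(object$scaler)) X <- scale_apply(X, object$scaler)
  df <- data.frame(X)
  pred <- switch(
    object$spec$family,
    DT = predict(object$model, df, type = "class"),
    # K is odd and the problem binary, so no random tie-breaks occur
    KNN = class::knn(object$model$train, X, object$model$cl,
                     k = object$model$k),
    SVM_linear = predict(object$model, X),
    SVM_RBF = predict(object$model, X),
    ADA = predict_adaboost(object$model, X),
    RF = predict(object$model, data = df, num.threads = 1)$predictions,
    ANN = predict(object$model, df, type = "class"))
  as.character(pred)
}

# Discrete AdaBoost.M1 over depth-1 rpart stumps.  Weighted stumps are
# refit sequentially; a stump that already separates the weighted sample
# perfectly ends the loop with a capped vote weight.
fit_adaboost <- function(X, y, n_estimators) {
  n <- nrow(X)
  df <- data.frame(X)
  df$.y <- y
  w <- rep(1 / n, n)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  m_used <- 0L
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = 0, xval = 0,
                          minsplit = 2, minbucket = 1))
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y])
    if (err >= 0.5) {                 # no better than weighted chance: stop
      if (m_used == 0L) { stumps[[1]] <- fit; alphas[1] <- 0; m_used <- 1L }
      break
    }
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    m_used <- m
    if (err <= 1e-10) break           # perfect stump
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps[seq_len(m_used)], alphas = alphas[seq_len(m_used)],
       levels = levels(y))
}

predict_adaboost <- function(model, X) {
  df <- data.frame(X)
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == "AF", 1, -1)
  }
  factor(ifelse(score > 0, "AF", "SR"), levels = model$levels)
}
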