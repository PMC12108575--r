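#' The five-classifier roster
#'
#' Benchmarked model families, in roster order (used as the final
#' tie-break in model selection): logistic regression, random forest,
#' RBF-kernel SVM, gradient boosting, and AdaBoost. All models run
#' with their library-default hyperparameters — no tuning is
#' performed anywhere in the pipeline.
#'
#' @return Character vector of classifier names.
#' @export
classifier_roster <- function() {
  c("logistic_regression", "random_forest", "svm", "gradient_boosting", "adaboost")
}

#' Train one classifier under the uniform interface
#'
#' Fits the named model on a transformed samples-by-features matrix
#' and wraps it so every family exposes the same surface: a
#' continuous score per sample (a probability where the library
#' supplies one, a monotonically mapped decision value for the SVM —
#' AUC is rank-invariant, so no calibration is attempted) and a class
#' call at score 0.5.
#'
#' @param name One of [classifier_roster()].
#' @param x Numeric samples-by-features matrix (transformed).
#' @param y Class labels ([sample_labels()] or vector aligned with
#'   rows of `x`); both classes must be present.
#' @param seed Integer seed; fits are deterministic given it.
#' @return An `efscv_model` object with a [predict()] method.
#' @export
train_classifier <- function(name, x, y, seed = 1L) {
  name <- match.arg(name, classifier_roster())
  x <- as.matrix(x)
  by <- binary_y(y)
  if (length(unique(by$y01)) < 2) abort("Both classes must be present in `y`.")
  set.seed(seed)
  fit <- switch(name,
    logistic_regression = fit_logistic(x, by$y01),
    random_forest = fit_rf(x, by$labels, by$positive),
    svm = fit_svm(x, by$labels, by$positive),
    gradient_boosting = fit_xgb(x, by$y01),
    adaboost = fit_adaboost(x, by$y01)
  )
  structure(list(name = name, fit = fit, positive = by$positive,
                 negative = by$negative, features = colnames(x), seed = seed),
            class = "efscv_model")
}

#' Predict scores and class calls
#'
#' @param object An `efscv_model`.
#' @param newdata Samples-by-features matrix with the training
#'   feature columns.
#' @param ... Unused.
#' @return A tibble with `score` (continuous, higher = more
#'   positive-class) and `class` (call at score 0.5).
#' @export
predict.efscv_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  score <- object$fit$score(newdata)
  tibble::tibble(
    score = as.numeric(score),
    class = ifelse(score >= 0.5, object$positive, object$negative)
  )
}

#' @export
print.efscv_model <- function(x, ...) {
  cat(sprintf("<efscv_model> %s on %d feature(s), positive class '%s'\n",
              x$name, length(x$features), x$positive))
  invisible(x)
}

## -- fitters ---------------------------------------------------------------
## each returns list(score = function(newx) -> numeric in score space)

fit_logistic <- function(x, y01) {
  xd <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(xd, y01, family = binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(score = function(newx) {
    as.vector(stats::plogis(cbind(1, newx) %*% beta))
  })
}

fit_rf <- function(x, labels, positive) {
  lv <- sort(unique(labels))
  rf <- randomForest::randomForest(x = x, y = factor(labels, levels = lv))
  list(score = function(newx) {
    p <- predict(rf, newx, type = "prob")
    p[, colnames(p) == positive, drop = TRUE]
  }, model = rf)
}

fit_svm <- function(x, labels, positive) {
  lv <- sort(unique(labels))
  fit <- e1071::svm(x = x, y = factor(labels, levels = lv), kernel = "radial",
                    cost = 1, scale = FALSE)
  list(score = function(newx) {
    pr <- predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    d <- if (identical(first, positive)) dv[, 1] else -dv[, 1]
    stats::plogis(d)  # monotone map onto [0,1] so the 0.5 call = sign rule
  })
}

fit_xgb <- function(x, y01) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 6, eta = 0.3,
                  nthread = 1),
    data = dtrain, nrounds = 100, verbose = 0
  )
  list(score = function(newx) {
    predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
  })
}

## Discrete AdaBoost (SAMME / AdaBoost.M1 on +/-1 labels) over
## depth-1 rpart stumps, 50 rounds, unit learning rate. Column names
## are remapped to syntactic ones so rpart's formula interface never
## chokes on field-style feature IDs.
fit_adaboost <- function(x, y01, n_rounds = 50) {
  ypm <- 2 * y01 - 1
  vnames <- paste0("V", seq_len(ncol(x)))
  df <- as.data.frame(x)
  colnames(df) <- vnames
  df$.y <- factor(ypm, levels = c(-1, 1))
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = -1, xval = 0)
  for (m in seq_len(n_rounds)) {
    st <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                       control = ctrl)
    h <- as.numeric(as.character(predict(st, df, type = "class")))
    err <- sum(w[h != ypm])
    if (err >= 0.5) {
      if (length(stumps) == 0) { stumps[[1]] <- st; alphas[1] <- 0 }
      break
    }
    alpha <- if (err <= 1e-12) 10 else 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- st
    alphas[length(alphas) + 1] <- alpha
    if (err <= 1e-12) break
    w <- w * exp(-alpha * ypm * h)
    w <- w / sum(w)
  }
  list(score = function(newx) {
    nd <- as.data.frame(newx)
    colnames(nd) <- vnames
    f <- rep(0, nrow(nd))
    for (m in seq_along(stumps)) {
      h <- as.numeric(as.character(predict(stumps[[m]], nd, type = "class")))
      f <- f + alphas[m] * h
    }
    stats::plogis(2 * f)
  })
}
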