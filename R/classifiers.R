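CLASSIFIER_NAMES <- c("SVM", "LDA", "RF", "LR", "LRLasso", "AdaBoost",
                      "DT", "GP", "NB")

# Discrete AdaBoost (SAMME) over decision stumps.
fit_adaboost <- function(x, y, n_rounds = 50) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1,
                                                       minsplit = 2,
                                                       xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 0.5 || err <= 1e-10) {
      if (err <= 1e-10) {
        stumps[[length(stumps) + 1]] <- fit
        alphas <- c(alphas, 10)
      }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x)
  if (!length(model$stumps)) return(rep(0.5, nrow(df)))
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    f <- f + model$alphas[m] * (2 * pred - 1)
  }
  plogis(2 * f / sum(model$alphas))
}

#' Train a binary classifier returning ranking scores
#'
#' Wraps the nine classifiers of the model-exploration grid: SVM (RBF,
#' probability output), linear discriminant analysis, random forest,
#' logistic regression, L1-regularized logistic regression (LASSO; with
#' a single feature the unpenalized fit is used), discrete AdaBoost over
#' decision stumps, a decision tree, a Gaussian-process classifier and
#' Gaussian naive Bayes. All return continuous scores in `[0, 1]`
#' (probability of class 1), and the fit is deterministic given `seed`.
#'
#' @param name classifier name, one of
#'   `r paste(CLASSIFIER_NAMES, collapse = ", ")`.
#' @param x training matrix (cases x features).
#' @param y binary 0/1 labels, each class with >= 2 cases.
#' @param seed integer controlling classifier-internal randomness.
#' @return A `trained_classifier`; score new data with
#'   `predict(object, newdata)`.
#' @export
train_classifier <- function(name, x, y, seed = 0L) {
  if (!name %in% CLASSIFIER_NAMES)
    stop("unknown classifier: ", name, " (available: ",
         paste(CLASSIFIER_NAMES, collapse = ", "), ")")
  if (min(table(y)) < 2) stop("need >= 2 cases per class")
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(seed, switch(
    name,
    SVM = e1071::svm(x, yf, probability = TRUE, kernel = "radial",
                     scale = FALSE),
    LDA = suppressWarnings(MASS::lda(x, grouping = yf)),
    RF = randomForest::randomForest(x, yf, ntree = 300),
    LR = suppressWarnings(glm.fit(cbind(1, x), y,
                                  family = binomial())),
    LRLasso = if (ncol(x) >= 2) {
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1, nfolds = 5)
    } else {
      suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
    },
    AdaBoost = fit_adaboost(x, y),
    DT = {
      df <- data.frame(x); df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 5, xval = 0))
    },
    GP = suppressWarnings(kernlab::gausspr(x, yf, kernel = "rbfdot",
                                           type = "classification")),
    NB = e1071::naiveBayes(data.frame(x), yf)))
  structure(list(name = name, fit = fit, p = ncol(x),
                 features = colnames(x)),
            class = "trained_classifier")
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x)))
    x <- x[, object$features, drop = FALSE]
  fit <- object$fit
  scores <- switch(
    object$name,
    SVM = {
      pr <- predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    LDA = predict(fit, x)$posterior[, "1"],
    RF = predict(fit, x, type = "prob")[, "1"],
    LR = plogis(drop(cbind(1, x) %*% coef(fit))),
    LRLasso = if (inherits(fit, "cv.glmnet")) {
      drop(predict(fit, x, s = "lambda.min", type = "response"))
    } else {
      plogis(drop(cbind(1, x) %*% coef(fit)))
    },
    AdaBoost = predict_adaboost(fit, x),
    DT = predict(fit, data.frame(x), type = "prob")[, "1"],
    GP = kernlab::predict(fit, x, type = "probabilities")[, "1"],
    NB = predict(fit, data.frame(x), type = "raw")[, "1"])
  unname(pmin(pmax(as.numeric(scores), 0), 1))
}
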