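#' Candidate learners for the super learner
#'
#' A learner is a named pair of fit/predict functions able to estimate a
#' conditional probability model for either task: `"binary_outcome"` (fit
#' returns `P(Y = 1 | X)`) or `"multiclass_treatment"` (fit returns a row-
#' stochastic matrix over treatment levels).  [sl_learner()] builds custom
#' learners; the `lrn_*` constructors wrap the stock library: the marginal
#' rate, main-terms (multinomial) logistic regression, L1-regularised
#' regression, random forests and gradient-boosted trees.
#'
#' @param name unique learner name.
#' @param fit `function(X, y, task)` returning a fitted model; `X` is a
#'   numeric matrix, `y` a 0/1 vector (binary task) or factor (multiclass).
#' @param predict `function(model, X, task)` returning a probability vector
#'   (binary) or a row-stochastic matrix with one column per class level.
#' @return an `sl_learner` object.
#' @name learners
NULL

#' @rdname learners
#' @export
sl_learner <- function(name, fit, predict) {
  stopifnot(is.character(name), is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict),
            class = "sl_learner")
}

#' @rdname learners
#' @export
lrn_mean <- function() {
  sl_learner(
    "mean",
    fit = function(X, y, task) {
      if (task == "binary_outcome") mean(y) else prop.table(table(y))
    },
    predict = function(model, X, task) {
      n <- nrow(X)
      if (task == "binary_outcome") rep(model, n)
      else matrix(rep(as.numeric(model), each = n), nrow = n,
                  dimnames = list(NULL, names(model)))
    }
  )
}

#' @rdname learners
#' @export
lrn_glm <- function() {
  sl_learner(
    "glm",
    fit = function(X, y, task) {
      if (task == "binary_outcome") {
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                       family = stats::binomial())
      } else {
        df <- data.frame(.y = y, X, check.names = FALSE)
        nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                       MaxNWts = 100000)
      }
    },
    predict = function(model, X, task) {
      if (task == "binary_outcome") {
        plogis(drop(cbind(1, X) %*% model$coefficients))
      } else {
        df <- data.frame(X, check.names = FALSE)
        p <- predict(model, newdata = df, type = "probs")
        lv <- model$lev
        if (is.null(dim(p))) {  # two-class multinom returns P(second level)
          p <- cbind(1 - p, p)
          colnames(p) <- lv
        }
        p[, lv, drop = FALSE]
      }
    }
  )
}

#' @rdname learners
#' @param alpha elastic-net mixing parameter (1 = lasso).
#' @param nfolds internal folds for the regularisation path.
#' @export
lrn_glmnet <- function(alpha = 1, nfolds = 5) {
  sl_learner(
    sprintf("glmnet_a%g", alpha),
    fit = function(X, y, task) {
      fam <- if (task == "binary_outcome") "binomial" else "multinomial"
      glmnet::cv.glmnet(X, y, family = fam, alpha = alpha, nfolds = nfolds)
    },
    predict = function(model, X, task) {
      p <- predict(model, newx = X, s = "lambda.min", type = "response")
      if (task == "binary_outcome") drop(p) else {
        m <- p[, , 1]
        m / rowSums(m)
      }
    }
  )
}

#' @rdname learners
#' @param num.trees,min.node.size forest size and leaf size.
#' @export
lrn_ranger <- function(num.trees = 300, min.node.size = 20) {
  sl_learner(
    "ranger",
    fit = function(X, y, task) {
      yy <- if (task == "binary_outcome") factor(y, levels = c(0, 1)) else y
      ranger::ranger(x = as.data.frame(X), y = yy, probability = TRUE,
                     num.trees = num.trees, min.node.size = min.node.size,
                     num.threads = 1, seed = sample.int(.Machine$integer.max, 1))
    },
    predict = function(model, X, task) {
      p <- predict(model, data = as.data.frame(X),
                   num.threads = 1)$predictions
      if (task == "binary_outcome") p[, "1"] else p
    }
  )
}

#' @rdname learners
#' @param nrounds,eta,max_depth boosting rounds, learning rate, tree depth.
#' @export
lrn_xgboost <- function(nrounds = 100, eta = 0.1, max_depth = 3) {
  sl_learner(
    "xgboost",
    fit = function(X, y, task) {
      if (task == "binary_outcome") {
        dm <- xgboost::xgb.DMatrix(X, label = y)
        pars <- list(objective = "binary:logistic", eta = eta,
                     max_depth = max_depth, nthread = 1)
        lv <- NULL
      } else {
        lv <- levels(y)
        dm <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
        pars <- list(objective = "multi:softprob", num_class = length(lv),
                     eta = eta, max_depth = max_depth, nthread = 1)
      }
      m <- xgboost::xgb.train(params = pars, data = dm, nrounds = nrounds,
                              verbose = 0)
      list(model = m, levels = lv)
    },
    predict = function(model, X, task) {
      p <- predict(model$model, newdata = xgboost::xgb.DMatrix(X))
      if (task == "binary_outcome") as.numeric(p)
      else {
        m <- if (is.matrix(p)) p
             else matrix(p, ncol = length(model$levels), byrow = TRUE)
        colnames(m) <- model$levels
        m
      }
    }
  )
}

#' Default learner libraries
#'
#' The stock library: marginal rate, main-terms (multinomial) logistic
#' regression, lasso, random forest, gradient boosting.  Smaller custom
#' libraries are often preferable for repeated simulation fits.
#'
#' @param task `"binary_outcome"` or `"multiclass_treatment"`.
#' @return list of `sl_learner` objects.
#' @export
default_library <- function(task = "binary_outcome") {
  list(lrn_mean(), lrn_glm(), lrn_glmnet(), lrn_ranger(), lrn_xgboost())
}
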