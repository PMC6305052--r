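# Feature-based control-group classifiers (SVM, random forest) trained on
# the clinical feature table.

feature_matrix <- function(features) {
  x <- features
  if (is.data.frame(x)) {
    x <- x[, setdiff(colnames(x), c("result", "Result", "label")), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class")
  }
}

#' Fit the SVM baseline
#'
#' Radial-kernel support vector machine with the tuned hyperparameters
#' `C = 1000`, `gamma = 1e-4` (the optimum of the reference grid search;
#' see [grid_search()]), via [e1071::svm()]. Features are z-scored on the
#' training data (and test data are scaled with the training statistics);
#' without this, an rbf kernel with so small a gamma is degenerate on raw
#' feature scales. Constant feature columns are excluded from scaling
#' with a warning.
#'
#' @param features feature data frame or matrix (a `result`/`label`
#'   column, if present, is dropped).
#' @param labels integer labels 0/1.
#' @param kernel,C,gamma SVM hyperparameters.
#' @return object of class `"ctg_svm"`.
#' @export
fit_svm <- function(features, labels, kernel = "radial", C = 1000,
                    gamma = 1e-4) {
  x <- feature_matrix(features)
  y <- factor(labels, levels = c(0, 1))
  check_two_classes(labels)
  sds <- apply(x, 2, stats::sd)
  scale_cols <- sds > 0
  if (any(!scale_cols)) {
    warning("constant feature column(s): ",
            paste(colnames(x)[!scale_cols], collapse = ", "),
            "; excluded from scaling")
  }
  fit <- e1071::svm(x, y, kernel = kernel, cost = C, gamma = gamma,
                    scale = scale_cols)
  structure(list(fit = fit, columns = colnames(x),
                 hyper = list(kernel = kernel, C = C, gamma = gamma)),
            class = "ctg_svm")
}

#' @export
predict.ctg_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata)[, object$columns, drop = FALSE]
  pred <- predict(object$fit, x, decision.values = TRUE)
  if (type == "class") {
    as.integer(as.character(pred))
  } else {
    dv <- drop(attr(pred, "decision.values"))
    # orient the score so larger means class 1
    if (grepl("^1/0", colnames(attr(pred, "decision.values"))[1])) dv else -dv
  }
}

#' @export
print.ctg_svm <- function(x, ...) {
  cat(sprintf("SVM baseline (kernel %s, C = %g, gamma = %g), %d support vectors\n",
              x$hyper$kernel, x$hyper$C, x$hyper$gamma, x$fit$tot.nSV))
  invisible(x)
}

#' Fit the random-forest baseline
#'
#' @param features feature data frame or matrix.
#' @param labels integer labels 0/1.
#' @param ntree number of trees (default 100).
#' @param seed integer seed (forest growth is stochastic).
#' @param ... passed to [randomForest::randomForest()].
#' @return object of class `"ctg_rf"`.
#' @export
fit_rf <- function(features, labels, ntree = 100, seed = 1L, ...) {
  x <- feature_matrix(features)
  y <- factor(labels, levels = c(0, 1))
  check_two_classes(labels)
  fit <- with_seed(seed, randomForest::randomForest(x, y, ntree = ntree, ...))
  structure(list(fit = fit, columns = colnames(x), ntree = ntree),
            class = "ctg_rf")
}

#' @export
predict.ctg_rf <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata)[, object$columns, drop = FALSE]
  if (type == "class") {
    as.integer(as.character(predict(object$fit, x)))
  } else {
    predict(object$fit, x, type = "prob")[, "1"]
  }
}

#' @export
print.ctg_rf <- function(x, ...) {
  cat(sprintf("Random-forest baseline: %d trees, OOB error %.3f\n",
              x$ntree, utils::tail(x$fit$err.rate[, "OOB"], 1)))
  invisible(x)
}

#' Exhaustive grid search for SVM hyperparameters
#'
#' Evaluates every (kernel, C, gamma) candidate by stratified inner
#' cross-validated accuracy of [fit_svm()]. Ties are broken toward the
#' smaller `C`, then the larger `gamma` (preferring the less complex,
#' smoother model).
#'
#' @param features feature data frame or matrix.
#' @param labels integer labels 0/1.
#' @param kernels,Cs,gammas candidate values; the defaults bracket the
#'   reference optimum `{rbf, C = 1000, gamma = 1e-4}`.
#' @param k inner-CV fold count.
#' @param seed fold-assignment seed.
#' @return list with `best` (kernel, C, gamma), `accuracy` and the full
#'   `results` data frame.
#' @export
grid_search <- function(features, labels, kernels = c("radial", "linear"),
                        Cs = c(1, 10, 100, 1000),
                        gammas = c(1e-2, 1e-3, 1e-4, 1e-5),
                        k = 5, seed = 1L) {
  if (length(kernels) == 0 || length(Cs) == 0 || length(gammas) == 0) {
    stop("candidate grid is empty")
  }
  check_two_classes(labels)
  if (k > min(table(labels))) {
    stop("fold count exceeds the support of the rarer class")
  }
  folds <- kfold(labels, k = k, seed = seed)
  grid <- expand.grid(kernel = kernels, C = Cs, gamma = gammas,
                      stringsAsFactors = FALSE)
  x <- feature_matrix(features)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    accs <- vapply(folds, function(fo) {
      fit <- suppressWarnings(
        fit_svm(x[fo$train, , drop = FALSE], labels[fo$train],
                kernel = grid$kernel[i], C = grid$C[i], gamma = grid$gamma[i]))
      mean(predict(fit, x[fo$test, , drop = FALSE]) == labels[fo$test])
    }, 1.0)
    mean(accs)
  }, 1.0)
  ord <- order(-grid$accuracy, grid$C, -grid$gamma)
  best <- grid[ord[1], ]
  list(best = list(kernel = best$kernel, C = best$C, gamma = best$gamma),
       accuracy = best$accuracy, results = grid)
}
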