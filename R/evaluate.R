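# Splitting, cross-validation, classification metrics and ROC/AUC.

#' Stratified train/test/validation split
#'
#' Splits indices into disjoint, exhaustive train/test/validation sets in
#' the given proportions (default 60/20/20), stratified by label: within
#' each class the split sizes are the largest-remainder rounding of the
#' class size times the fractions, so every class appears in every split
#' in (as near as possible) the global proportions.
#'
#' @param labels integer label vector (the records to split).
#' @param train_fraction,test_fraction,validation_fraction proportions
#'   summing to 1.
#' @param stratified stratify by label (default TRUE).
#' @param seed shuffle seed.
#' @return list of integer index vectors `train`, `test`, `validation`.
#' @export
#' @examples
#' s <- split_dataset(rep(0:1, 500), seed = 1)
#' lengths(s)  # 600, 200, 200
split_dataset <- function(labels, train_fraction = 0.60,
                          test_fraction = 0.20,
                          validation_fraction = 0.20,
                          stratified = TRUE, seed = 1L) {
  fr <- c(train_fraction, test_fraction, validation_fraction)
  if (abs(sum(fr) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(labels)
  if (n < 5) stop("need at least 5 records to split")
  largest_remainder <- function(m, fr) {
    raw <- m * fr
    base <- floor(raw)
    extra <- m - sum(base)
    if (extra > 0) {
      add <- order(raw - base, decreasing = TRUE)[seq_len(extra)]
      base[add] <- base[add] + 1L
    }
    as.integer(base)
  }
  groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  out <- list(train = integer(), test = integer(), validation = integer())
  with_seed(seed, {
    for (ix in groups) {
      ix <- sample(ix)
      sizes <- largest_remainder(length(ix), fr)
      if (any(sizes == 0)) stop("a split would be empty for some class")
      ends <- cumsum(sizes)
      out$train <- c(out$train, ix[seq_len(ends[1])])
      out$test <- c(out$test, ix[(ends[1] + 1L):ends[2]])
      out$validation <- c(out$validation, ix[(ends[2] + 1L):ends[3]])
    }
  })
  lapply(out, sort)
}

#' Stratified k-fold cross-validation folds
#'
#' @param labels integer label vector.
#' @param k fold count (default 5).
#' @param seed shuffle seed.
#' @return list of `k` lists with `train` and `test` index vectors; each
#'   index appears in exactly one test fold.
#' @export
kfold <- function(labels, k = 5, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("k exceeds the number of records")
  assign_fold <- integer(n)
  with_seed(seed, {
    for (ix in split(seq_len(n), labels)) {
      ix <- sample(ix)
      assign_fold[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(assign_fold != f), test = which(assign_fold == f))
  })
}

#' Classification metrics (per-class and weighted averages)
#'
#' Per-class precision, recall and F1 from the confusion table, plus the
#' support-weighted averages (the classification-report convention) and
#' overall accuracy. A class absent from `y_true` has undefined per-class
#' metrics (`NaN`) and zero weight in the averages.
#'
#' @param y_true,y_pred equal-length 0/1 label vectors.
#' @return list of class `"ctg_metrics"`: `per_class` data frame
#'   (label, precision, recall, f1, support), `avg_precision`,
#'   `avg_recall`, `avg_f1`, `accuracy`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(c(y_true, y_pred) %in% c(0, 1))) stop("labels must be 0/1")
  per <- lapply(c(0, 1), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    support <- sum(y_true == cl)
    precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
    recall <- if (support == 0) NaN else tp / (tp + fn)
    f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
      if (support == 0) NaN else 0
    } else 2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1, support = support)
  })
  tab <- do.call(rbind, per)
  support <- tab[, "support"]
  wavg <- function(v) {
    ok <- support > 0 & !is.nan(v)
    sum(v[ok] * support[ok]) / sum(support[ok])
  }
  structure(list(
    per_class = data.frame(label = c(0L, 1L), precision = tab[, "precision"],
                           recall = tab[, "recall"], f1 = tab[, "f1"],
                           support = as.integer(support)),
    avg_precision = wavg(tab[, "precision"]),
    avg_recall = wavg(tab[, "recall"]),
    avg_f1 = wavg(tab[, "f1"]),
    accuracy = mean(y_true == y_pred)
  ), class = "ctg_metrics")
}

#' @export
print.ctg_metrics <- function(x, digits = 4, ...) {
  cat("Label  Precision  Recall  F1-score  Support\n")
  for (i in 1:2) {
    r <- x$per_class[i, ]
    cat(sprintf("%5d  %9.4f  %6.4f  %8.4f  %7d\n", r$label, r$precision,
                r$recall, r$f1, r$support))
  }
  cat(sprintf("Avg/total  %.4f  %.4f  %.4f   (accuracy %.4f)\n",
              x$avg_precision, x$avg_recall, x$avg_f1, x$accuracy))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped into a single step) and reports the (false-positive-rate,
#' true-positive-rate) path from (0, 0) to (1, 1) with its trapezoidal
#' area. The AUC equals the Mann-Whitney probability that a random
#' positive outscores a random negative (ties counting one half).
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores real-valued scores, larger favouring class 1.
#' @return object of class `"roc_curve"`: data frame `points` (fpr, tpr)
#'   and `auc`.
#' @export
roc_curve_auc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2) stop("both classes must be present")
  if (length(y_true) != length(scores)) stop("length mismatch")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  npos <- sum(y == 1); nneg <- sum(y == 0)
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied score group
  tpr <- c(0, cumsum(y == 1)[keep] / npos)
  fpr <- c(0, cumsum(y == 0)[keep] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  if (add) {
    graphics::lines(x$points$fpr, x$points$tpr, ...)
  } else {
    plot(x$points$fpr, x$points$tpr, type = "l", xlim = c(0, 1),
         ylim = c(0, 1), xlab = "False positive rate",
         ylab = "True positive rate", ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Vertically averaged ROC curve
#'
#' Interpolates every member curve's TPR on a common FPR grid (101 points
#' from 0 to 1) and averages pointwise; the reported AUC is the
#' arithmetic mean of the member AUCs.
#'
#' @param curves nonempty list of `roc_curve` objects.
#' @return a `roc_curve` (the mean curve).
#' @export
mean_roc <- function(curves) {
  if (length(curves) == 0) stop("empty curve list")
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(curves, function(cu) {
    stats::approx(cu$points$fpr, cu$points$tpr, xout = grid,
                  method = "linear", rule = 2, ties = max)$y
  }, numeric(101))
  structure(list(points = data.frame(fpr = grid, tpr = rowMeans(tprs)),
                 auc = mean(vapply(curves, `[[`, 1.0, "auc"))),
            class = "roc_curve")
}

#' Evaluate a classifier under holdout or k-fold protocols
#'
#' Runs the chosen protocol and aggregates [compute_metrics()] and
#' [roc_curve_auc()] per fold plus the vertically averaged mean ROC.
#'
#' @param fit_fun function `(x_train, y_train) -> model`.
#' @param score_fun function `(model, x_test) -> scores` (larger favours
#'   class 1).
#' @param x inputs indexable by `x[idx]` (list) or `x[idx, ]` (matrix or
#'   data frame).
#' @param y 0/1 labels.
#' @param protocol `"kfold"` (default, the control-group protocol) or
#'   `"holdout"` (60/20/20; the test split is scored).
#' @param k fold count for `"kfold"`.
#' @param seed split/fold seed.
#' @return object of class `"eval_report"`: `folds` (list of per-fold
#'   `metrics` and `roc`), `summary` data frame (one row per fold:
#'   accuracy, weighted precision/recall/F1, AUC), `mean_roc`,
#'   `mean_auc`, `accuracy` (pooled over test predictions).
#' @export
evaluate_model <- function(fit_fun, score_fun, x, y,
                           protocol = c("kfold", "holdout"), k = 5,
                           seed = 1L) {
  protocol <- match.arg(protocol)
  y <- as.integer(y)
  subset_x <- function(x, idx) {
    if (is.matrix(x) || is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  }
  pairs <- if (protocol == "kfold") {
    kfold(y, k = k, seed = seed)
  } else {
    s <- split_dataset(y, seed = seed)
    list(list(train = s$train, test = s$test))
  }
  folds <- list()
  pooled_true <- integer(); pooled_pred <- integer()
  for (i in seq_along(pairs)) {
    fo <- pairs[[i]]
    model <- fit_fun(subset_x(x, fo$train), y[fo$train])
    scores <- score_fun(model, subset_x(x, fo$test))
    # probabilities classify at 0.5, signed decision values at 0
    thr <- if (all(scores >= 0 & scores <= 1)) 0.5 else 0
    pred <- as.integer(scores > thr)
    m <- compute_metrics(y[fo$test], pred)
    r <- roc_curve_auc(y[fo$test], scores)
    folds[[i]] <- list(metrics = m, roc = r, test = fo$test)
    pooled_true <- c(pooled_true, y[fo$test])
    pooled_pred <- c(pooled_pred, pred)
  }
  summary_df <- do.call(rbind, lapply(seq_along(folds), function(i) {
    m <- folds[[i]]$metrics
    data.frame(fold = i, accuracy = m$accuracy,
               precision = m$avg_precision, recall = m$avg_recall,
               f1 = m$avg_f1, auc = folds[[i]]$roc$auc)
  }))
  mroc <- mean_roc(lapply(folds, `[[`, "roc"))
  structure(list(protocol = protocol, folds = folds, summary = summary_df,
                 mean_roc = mroc, mean_auc = mroc$auc,
                 accuracy = mean(pooled_true == pooled_pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s, %d fold%s): accuracy %.4f, mean AUC %.4f\n",
              x$protocol, nrow(x$summary),
              if (nrow(x$summary) > 1) "s" else "", x$accuracy, x$mean_auc))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.eval_report <- function(object, ...) {
  print(object)
  invisible(object)
}
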