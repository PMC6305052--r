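test_that("stratified 60/20/20 split has exact sizes and strata", {
  y <- rep(c(0L, 1L), each = 500)
  sp <- split_dataset(y, seed = 2)
  expect_length(sp$train, 600)
  expect_length(sp$validation, 200)
  expect_length(sp$test, 200)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$validation, sp$test), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_along(y))
  # stratification: class shares preserved within one sample
  for (part in sp) {
    expect_lte(abs(sum(y[part] == 1) - length(part) / 2), 1)
  }
  # reproducible
  expect_identical(split_dataset(y, seed = 2), sp)
})

test_that("split handles uneven class sizes by largest remainder", {
  y <- c(rep(0L, 35), rep(1L, 15))
  sp <- split_dataset(y, seed = 3)
  expect_equal(lengths(sp)[["train"]], 30L)
  expect_equal(lengths(sp)[["test"]], 10L)
  expect_equal(lengths(sp)[["validation"]], 10L)
  expect_setequal(unlist(sp), 1:50)
  expect_equal(sum(y[sp$train] == 1), 9)
  expect_error(split_dataset(c(0L, 0L, 0L, 1L, 1L), seed = 1),
               "empty")
})

test_that("k-fold partitions are exclusive, exhaustive and stratified", {
  y <- rep(c(0L, 1L), each = 25)
  f <- kfold(y, k = 5, seed = 4)
  expect_length(f, 5)
  tests <- lapply(f, `[[`, "test")
  expect_setequal(unlist(tests), seq_along(y))
  expect_equal(sum(lengths(tests)), 50)
  for (fo in f) {
    expect_length(fo$test, 10)
    expect_equal(sum(y[fo$test] == 1), 5)
    expect_setequal(c(fo$train, fo$test), seq_along(y))
    expect_length(intersect(fo$train, fo$test), 0)
  }
  expect_identical(kfold(y, k = 5, seed = 4), f)
  # n = 10, k = 5 gives test folds of exactly 2
  f2 <- kfold(rep(c(0L, 1L), 5), k = 5, seed = 5)
  expect_true(all(lengths(lapply(f2, `[[`, "test")) == 2))
  expect_error(kfold(rep(0L, 3), k = 5), "exceeds")
})

test_that("classification metrics match a hand-counted example", {
  y_true <- c(0L, 0L, 1L, 1L)
  y_pred <- c(0L, 1L, 1L, 1L)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.75)
  p1 <- m$per_class[m$per_class$label == 1, ]
  expect_equal(p1$precision, 2 / 3)
  expect_equal(p1$recall, 1.0)
  expect_equal(p1$f1, 2 * (2 / 3) / (1 + 2 / 3))
  p0 <- m$per_class[m$per_class$label == 0, ]
  expect_equal(p0$precision, 1.0)
  expect_equal(p0$recall, 0.5)
  # support-weighted averages
  expect_equal(m$avg_recall, 0.75)
})

test_that("metrics are symmetric under relabeling", {
  set.seed(6)
  y <- sample(0:1, 50, replace = TRUE)
  p <- sample(0:1, 50, replace = TRUE)
  m1 <- compute_metrics(y, p)
  m2 <- compute_metrics(1L - y, 1L - p)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$per_class$precision[m1$per_class$label == 0],
               m2$per_class$precision[m2$per_class$label == 1])
})

test_that("metrics agree with the counting oracle exhaustively and at random", {
  labs <- expand.grid(rep(list(0:1), 6))
  set.seed(7)
  for (i in sample(nrow(labs), 40)) {
    y <- as.integer(labs[i, ])
    p <- as.integer(labs[sample(nrow(labs), 1), ])
    m <- compute_metrics(y, p)
    o <- oracle_metrics(y, p)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$avg_precision, o$avg_precision)
    expect_equal(m$avg_recall, o$avg_recall)
    expect_equal(m$avg_f1, o$avg_f1)
    for (cl in c(0L, 1L)) {
      row <- m$per_class[m$per_class$label == cl, ]
      expect_equal(row$precision, unname(o$per[[as.character(cl)]]["precision"]))
      expect_equal(row$recall, unname(o$per[[as.character(cl)]]["recall"]))
    }
  }
})

test_that("AUC equals the pairwise-comparison oracle and pROC", {
  set.seed(8)
  for (rep in 1:10) {
    y <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(runif(40), 2)  # deliberate ties
    rc <- roc_curve_auc(y, s)
    expect_equal(rc$auc, oracle_auc(y, s))
    expect_equal(rc$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("AUC hits the perfect, anti-perfect and reflection identities", {
  y <- c(0L, 0L, 1L, 1L)
  expect_equal(roc_curve_auc(y, c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_curve_auc(y, c(0.9, 0.8, 0.2, 0.1))$auc, 0)
  set.seed(9)
  y2 <- sample(0:1, 30, replace = TRUE)
  s <- runif(30)
  expect_equal(roc_curve_auc(y2, s)$auc + roc_curve_auc(y2, -s)$auc, 1)
  # random scores on large n are near one half
  set.seed(10)
  yr <- sample(0:1, 4000, replace = TRUE)
  expect_lt(abs(roc_curve_auc(yr, runif(4000))$auc - 0.5), 0.05)
})

test_that("ROC curves start at (0,0), end at (1,1) and are monotone", {
  set.seed(11)
  y <- sample(0:1, 50, replace = TRUE)
  s <- runif(50)
  pts <- roc_curve_auc(y, s)$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_error(roc_curve_auc(rep(1L, 5), runif(5)), "both classes")
})

test_that("mean ROC averages member curves vertically", {
  y <- c(0L, 0L, 1L, 1L)
  r1 <- roc_curve_auc(y, c(0.1, 0.2, 0.8, 0.9))
  # identical members reproduce the member
  m_same <- mean_roc(list(r1, r1))
  expect_equal(m_same$auc, 1)
  ref <- approx(r1$points$fpr, r1$points$tpr, m_same$points$fpr,
                ties = max, rule = 2)$y
  expect_true(all(abs(m_same$points$tpr - ref) < 1e-9))
  # the mean AUC is the mean of member AUCs
  set.seed(12)
  y2 <- sample(0:1, 40, replace = TRUE)
  r2 <- roc_curve_auc(y2, runif(40))
  r3 <- roc_curve_auc(y2, runif(40))
  m <- mean_roc(list(r2, r3))
  expect_equal(m$auc, mean(c(r2$auc, r3$auc)))
  # envelope: the averaged curve lies between the members pointwise
  t2 <- approx(r2$points$fpr, r2$points$tpr, m$points$fpr,
               ties = max, rule = 2)$y
  t3 <- approx(r3$points$fpr, r3$points$tpr, m$points$fpr,
               ties = max, rule = 2)$y
  expect_true(all(m$points$tpr >= pmin(t2, t3) - 1e-9))
  expect_true(all(m$points$tpr <= pmax(t2, t3) + 1e-9))
  expect_error(mean_roc(list()), "empty")
})

test_that("evaluate_model runs stratified cross-validation end to end", {
  cl <- make_gaussian_clouds(100, seed = 13)
  rep5 <- evaluate_model(
    fit_fun = function(X, y) fit_svm(X, y),
    score_fun = function(m, X) predict(m, X, type = "score"),
    x = cl$x, y = cl$y, protocol = "kfold", k = 5, seed = 14)
  expect_s3_class(rep5, "eval_report")
  expect_equal(nrow(rep5$summary), 5)
  expect_gte(rep5$accuracy, 0.9)
  expect_gte(rep5$mean_auc, 0.9)
  expect_equal(rep5$mean_auc, mean(rep5$summary$auc))
})

test_that("evaluate_model under holdout scores exactly the test split", {
  cl <- make_gaussian_clouds(100, seed = 15)
  rep1 <- evaluate_model(
    fit_fun = function(X, y) fit_rf(X, y, seed = 16),
    score_fun = function(m, X) predict(m, X, type = "score"),
    x = cl$x, y = cl$y, protocol = "holdout", seed = 17)
  expect_equal(nrow(rep1$summary), 1)
  expect_length(rep1$folds[[1]]$test, 20)
  expect_identical(rep1$folds[[1]]$test,
                   split_dataset(cl$y, seed = 17)$test)
  expect_gte(rep1$accuracy, 0.9)
})
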