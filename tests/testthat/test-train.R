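# Correctness of the gradient engine and the training contracts.

numeric_grad_check <- function(net, x, Y, samples = 5, eps = 1e-5) {
  fw <- ctgkit:::net_forward(net, x, train = FALSE)
  gr <- ctgkit:::net_backward(net, fw$caches, fw$probs, Y)
  loss_at <- function(n) {
    ctgkit:::cross_entropy(ctgkit:::net_forward(n, x, FALSE)$probs, Y)
  }
  maxrel <- 0
  for (li in seq_along(net)) {
    if (is.null(net[[li]]$params)) next
    for (nm in names(net[[li]]$params)) {
      P <- net[[li]]$params[[nm]]
      for (k in sample(length(P), min(samples, length(P)))) {
        np <- net; np[[li]]$params[[nm]][k] <- P[k] + eps
        nn <- net; nn[[li]]$params[[nm]][k] <- P[k] - eps
        num <- (loss_at(np) - loss_at(nn)) / (2 * eps)
        ana <- gr[[li]][[nm]][k]
        maxrel <- max(maxrel, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
  }
  maxrel
}

test_that("convolutional gradients match finite differences", {
  set.seed(1)
  spec <- build_mknet("A", filters = c(2, 2, 2), fc_units = c(4, 3, 2),
                      input_shape = c(8, 12, 1))
  net <- ctgkit:::init_network(spec, c(8, 12, 1))
  x <- array(runif(8 * 12 * 3), c(8, 12, 1, 3))
  Y <- ctgkit:::one_hot(c(0L, 1L, 0L))
  expect_lt(numeric_grad_check(net, x, Y), 1e-5)
})

test_that("strided convolution gradients match finite differences", {
  set.seed(2)
  spec <- ctgkit:::model_spec("tiny", list(
    layer_spec("conv", kernel = c(3L, 3L), filters = 2L,
               stride = c(2L, 2L), activation = "relu"),
    layer_spec("flatten"),
    layer_spec("softmax", units = 2L, activation = "softmax")
  ), c(6, 8, 1))
  net <- ctgkit:::init_network(spec, c(6, 8, 1))
  x <- array(runif(6 * 8 * 2), c(6, 8, 1, 2))
  Y <- ctgkit:::one_hot(c(0L, 1L))
  expect_lt(numeric_grad_check(net, x, Y, samples = 8), 1e-5)
})

test_that("LSTM gradients match finite differences through time", {
  set.seed(3)
  spec <- build_mkrnn(units = 5, dropout = 0, recurrent_dropout = 0,
                      timesteps = 7)
  net <- ctgkit:::init_network(spec, c(7, 1))
  X <- matrix(runif(7 * 3), 7, 3)
  Y <- ctgkit:::one_hot(c(0L, 1L, 1L))
  expect_lt(numeric_grad_check(net, X, Y, samples = 10), 1e-4)
})

test_that("a separable image task is learned to perfect training accuracy", {
  toy <- make_toy_images(20, seed = 4)
  spec <- build_mknet("A", filters = c(2, 2, 2), fc_units = c(8, 4, 2))
  cfg <- train_config(epochs = 5, batch_size = 4, downscale = c(8, 48),
                      learning_rate = 5e-3, seed = 5)
  m <- train(spec, toy$x, toy$y, cfg)
  expect_s3_class(m, "ctg_model")
  expect_equal(nrow(m$history), 5)
  expect_equal(m$history$train_acc[5], 1.0)
  # loss non-increasing on the whole-run trend
  expect_lt(m$history$train_loss[5], m$history$train_loss[1])
})

test_that("training is reproducible from the seed and errors are raised", {
  toy <- make_toy_images(12, seed = 6)
  spec <- build_mknet("A", filters = c(2, 2, 2), fc_units = c(8, 4, 2))
  cfg <- train_config(epochs = 2, batch_size = 4, downscale = c(8, 48),
                      seed = 7)
  m1 <- train(spec, toy$x, toy$y, cfg)
  m2 <- train(spec, toy$x, toy$y, cfg)
  expect_identical(m1$history, m2$history)
  expect_error(train(spec, toy$x, rep(0L, 12), cfg), "single class")
  expect_error(train_config(epochs = 0), "epochs")
  short <- lapply(toy$x, function(im) im$pixels[, 1:1200])
  expect_error(train(spec, short, toy$y, cfg), "shape mismatch")
})

test_that("probability rows are normalized, deterministic and symmetric when untrained", {
  toy <- make_toy_images(8, seed = 8)
  spec <- build_mknet("A", filters = c(2, 2, 2), fc_units = c(8, 4, 2))
  cfg <- train_config(epochs = 1, batch_size = 4, downscale = c(8, 48),
                      seed = 9)
  m <- train(spec, toy$x, toy$y, cfg)
  p <- predict_proba(m, toy$x)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicated inputs give identical rows
  p2 <- predict_proba(m, c(toy$x[1], toy$x[1]))
  expect_equal(p2[1, ], p2[2, ])
  # zeroing the softmax head gives the uniform distribution
  m0 <- m
  last <- length(m0$net)
  m0$net[[last]]$params$W[] <- 0
  m0$net[[last]]$params$b[] <- 0
  pu <- predict_proba(m0, toy$x[1:2])
  expect_equal(as.numeric(pu), rep(0.5, 4))
})

test_that("MKRNN learns level-separable sequences", {
  set.seed(10)
  n <- 24
  y <- rep(c(0L, 1L), length.out = n)
  seqs <- lapply(seq_len(n), function(i) {
    base <- if (y[i] == 0) 120 else 170
    base + rnorm(120, sd = 2)
  })
  spec <- build_mkrnn(units = 8, dropout = 0, recurrent_dropout = 0,
                      timesteps = 120)
  cfg <- train_config(epochs = 12, batch_size = 8, learning_rate = 2e-2,
                      subsample = 1, seed = 11)
  m <- train(spec, seqs, y, cfg)
  expect_equal(m$input_kind, "sequence")
  p <- predict_proba(m, seqs)
  expect_gte(mean((p[, "1"] > 0.5) == y), 0.9)
})

test_that("augmentation keeps training viable on shift-invariant classes", {
  toy <- make_toy_images(12, seed = 12)
  spec <- build_mknet("A", filters = c(2, 2, 2), fc_units = c(8, 4, 2))
  cfg <- train_config(epochs = 4, batch_size = 4, downscale = c(8, 48),
                      learning_rate = 5e-3, augmentation = TRUE, seed = 13)
  m <- train(spec, toy$x, toy$y, cfg)
  expect_gte(m$history$train_acc[4], 0.9)
})
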