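# Input marshalling -------------------------------------------------------

# images: list of fhr_image / matrices, or a (h, w, n) array ->
# (h, w, 1, n) array, optionally mean-pooled by cfg$downscale
prepare_image_input <- function(x, downscale = c(1L, 1L)) {
  mats <- if (is.array(x) && length(dim(x)) == 3) {
    lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  } else if (is.list(x)) {
    lapply(x, function(im) if (inherits(im, "fhr_image")) im$pixels else im)
  } else stop("image input must be a list of images or a 3-D array")
  if (any(downscale > 1L)) {
    mats <- lapply(mats, downscale_pixels, fh = downscale[1], fw = downscale[2])
  }
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), TRUE))) {
    stop("shape mismatch: images have differing dimensions")
  }
  arr <- array(unlist(mats, use.names = FALSE), c(d[1], d[2], 1L, length(mats)))
  arr
}

# sequences: list of clean_signal / numeric vectors, or (T x n) matrix ->
# (T x n) matrix, subsampled and scaled to [0, 1] by (v - 80) / 120
prepare_sequence_input <- function(x, subsample = 1L) {
  M <- if (is.matrix(x)) x else {
    vs <- lapply(x, function(s) if (inherits(s, "clean_signal")) s$values else s)
    len <- unique(vapply(vs, length, 1L))
    if (length(len) != 1) stop("shape mismatch: sequences have differing lengths")
    matrix(unlist(vs, use.names = FALSE), nrow = len)
  }
  if (subsample > 1L) M <- M[seq.int(1L, nrow(M), by = subsample), , drop = FALSE]
  (M - 80) / 120
}

one_hot <- function(y) {
  Y <- matrix(0, 2L, length(y))
  Y[cbind(y + 1L, seq_along(y))] <- 1
  Y
}

# random horizontal shift of every sample in a (h, w, 1, n) batch
augment_batch <- function(xb, frac) {
  w <- dim(xb)[2]
  s <- floor(frac * w)
  if (s == 0) return(xb)
  for (i in seq_len(dim(xb)[4])) {
    d <- sample(seq.int(-s, s), 1)
    xb[, , 1L, i] <- shift_columns(xb[, , 1L, i], d)
  }
  xb
}

#' Train an MKNet or MKRNN classifier
#'
#' Minimizes two-class cross-entropy with minibatch RMSprop (or Adagrad)
#' using the package's own gradient engine. Image specs (MKNet) take a
#' list of [render_image()] outputs (optionally mean-pooled to a reduced
#' resolution via `cfg$downscale` for scale-rehearsal runs); sequence
#' specs (MKRNN) take cleaned traces, subsampled by `cfg$subsample` and
#' scaled to \[0, 1\]. With `cfg$augmentation` on, every image batch is
#' re-drawn each epoch with a random horizontal shift (see
#' [shift_augment()]). Reproducible given `cfg$seed`.
#'
#' @param spec a `model_spec` from [build_mknet()] or [build_mkrnn()].
#' @param x training inputs (see above).
#' @param y integer labels, 0 or 1, both classes present.
#' @param cfg a [train_config()].
#' @param validation optional list `list(x = , y = )` evaluated once per
#'   epoch; overrides `cfg$validation_fraction`.
#' @return object of class `"ctg_model"` with the layer parameters, the
#'   per-epoch `history` data frame (train/validation accuracy and loss)
#'   and the resolved configuration.
#' @export
train <- function(spec, x, y, cfg = train_config(), validation = NULL) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("training data contain a single class")
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  is_seq <- any(kinds == "lstm")
  set.seed(cfg$seed)
  if (is_seq) {
    X <- prepare_sequence_input(x, cfg$subsample)
    if (ncol(X) != length(y)) stop("shape mismatch: inputs vs labels")
    input_dim <- c(nrow(X), 1L)
    take <- function(X, idx) X[, idx, drop = FALSE]
    nobs <- ncol(X)
  } else {
    X <- prepare_image_input(x, cfg$downscale)
    if (dim(X)[4] != length(y)) stop("shape mismatch: inputs vs labels")
    exp_dim <- c(spec$input_shape[1] %/% cfg$downscale[1],
                 spec$input_shape[2] %/% cfg$downscale[2])
    if (!all(dim(X)[1:2] == exp_dim)) {
      stop(sprintf("shape mismatch: images are %d x %d, spec expects %d x %d",
                   dim(X)[1], dim(X)[2], exp_dim[1], exp_dim[2]))
    }
    input_dim <- dim(X)[1:3]
    take <- function(X, idx) X[, , , idx, drop = FALSE]
    nobs <- length(y)
  }

  val <- NULL
  train_idx <- seq_len(nobs)
  if (!is.null(validation)) {
    vx <- if (is_seq) prepare_sequence_input(validation$x, cfg$subsample)
          else prepare_image_input(validation$x, cfg$downscale)
    val <- list(x = vx, y = as.integer(validation$y))
  } else if (cfg$validation_fraction > 0) {
    hold <- unlist(lapply(split(train_idx, y), function(ix) {
      sample(ix, max(1L, round(length(ix) * cfg$validation_fraction)))
    }), use.names = FALSE)
    val <- list(x = take(X, hold), y = y[hold])
    train_idx <- setdiff(train_idx, hold)
  }
  Xtr <- take(X, train_idx)
  ytr <- y[train_idx]
  ntr <- length(ytr)

  net <- init_network(spec, input_dim)
  state <- make_opt_state(net)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(ntr)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq.int(1L, ntr, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, ntr)]
      xb <- take(Xtr, idx)
      if (!is_seq && cfg$augmentation) {
        xb <- augment_batch(xb, cfg$augment_cfg$width_shift_fraction)
      }
      Y <- one_hot(ytr[idx])
      fw <- net_forward(net, xb, train = TRUE)
      ep_loss <- ep_loss + cross_entropy(fw$probs, Y) * length(idx)
      ep_correct <- ep_correct + sum(max.col(t(fw$probs)) - 1L == ytr[idx])
      grads <- net_backward(net, fw$caches, fw$probs, Y)
      upd <- opt_update(net, grads, state, cfg$optimizer, cfg$learning_rate)
      net <- upd$net; state <- upd$state
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / ntr,
                      train_acc = ep_correct / ntr,
                      val_loss = NA_real_, val_acc = NA_real_)
    if (!is.null(val)) {
      pv <- net_forward(net, val$x, train = FALSE)$probs
      row$val_loss <- cross_entropy(pv, one_hot(val$y))
      row$val_acc <- mean(max.col(t(pv)) - 1L == val$y)
    }
    hist <- rbind(hist, row)
  }
  structure(list(spec = spec, net = net, cfg = cfg, history = hist,
                 input_kind = if (is_seq) "sequence" else "image",
                 input_dim = input_dim),
            class = "ctg_model")
}

#' Class-probability predictions
#'
#' @param model a fitted `ctg_model`.
#' @param x inputs in the same form used for training.
#' @param batch_size forward-pass chunk size.
#' @return numeric matrix, one row per input, columns `"0"` and `"1"`;
#'   rows are nonnegative and sum to 1.
#' @export
predict_proba <- function(model, x, batch_size = 256L) {
  if (model$input_kind == "sequence") {
    X <- prepare_sequence_input(x, model$cfg$subsample)
    n <- ncol(X)
    take <- function(idx) X[, idx, drop = FALSE]
    if (nrow(X) != model$input_dim[1]) stop("shape mismatch")
  } else {
    X <- prepare_image_input(x, model$cfg$downscale)
    n <- dim(X)[4]
    take <- function(idx) X[, , , idx, drop = FALSE]
    if (!all(dim(X)[1:3] == model$input_dim)) stop("shape mismatch")
  }
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("0", "1")))
  for (b0 in seq.int(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    out[idx, ] <- t(net_forward(model$net, take(idx), train = FALSE)$probs)
  }
  out
}

#' @export
predict.ctg_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p[, "1"] > 0.5)
}

#' @export
print.ctg_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained %s (%s input %s): %d epochs, final train acc %.3f%s\n",
              x$spec$name, x$input_kind,
              paste(x$input_dim, collapse = "x"),
              nrow(h), h$train_acc[nrow(h)],
              if (!is.na(h$val_acc[nrow(h)])) {
                sprintf(", val acc %.3f", h$val_acc[nrow(h)])
              } else ""))
  invisible(x)
}

#' @export
summary.ctg_model <- function(object, ...) {
  print(object)
  print(object$spec)
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Plot learning curves
#'
#' Accuracy and loss per epoch, training and (when recorded) validation.
#'
#' @param x a fitted `ctg_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ctg_model <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy",
                    main = paste(x$spec$name, "accuracy"), ...)
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1:2, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss",
                    main = paste(x$spec$name, "loss"), ...)
  invisible(x)
}
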