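#' Layer descriptor
#'
#' One entry of a model specification's layer stack (see [build_mknet()]
#' and [build_mkrnn()]). Only the fields relevant to the `kind` are used.
#'
#' @param kind one of `"conv"`, `"pool"`, `"dense"`, `"dropout"`,
#'   `"softmax"`, `"flatten"`, `"lstm"`.
#' @param kernel `(h, w)` kernel for conv/pool layers.
#' @param filters number of convolution filters.
#' @param stride `(h, w)` stride.
#' @param padding `"same"` or `"valid"` (conv layers here use `"same"`).
#' @param units output width for dense/softmax/lstm layers.
#' @param rate dropout fraction.
#' @param activation activation name (`"relu"`, `"softmax"`, `"tanh"`).
#' @param dropout,recurrent_dropout LSTM dropout fractions.
#' @return list of class `"layer_spec"`.
#' @export
layer_spec <- function(kind, kernel = NULL, filters = NULL,
                       stride = c(1L, 1L), padding = "same", units = NULL,
                       rate = NULL, activation = NULL,
                       dropout = NULL, recurrent_dropout = NULL) {
  kind <- match.arg(kind, c("conv", "pool", "dense", "dropout", "softmax",
                            "flatten", "lstm"))
  structure(list(kind = kind, kernel = kernel, filters = filters,
                 stride = stride, padding = padding, units = units,
                 rate = rate, activation = activation,
                 dropout = dropout, recurrent_dropout = recurrent_dropout),
            class = "layer_spec")
}

model_spec <- function(name, layers, input_shape, options = list()) {
  structure(list(name = name, layers = layers, input_shape = input_shape,
                 options = options),
            class = "model_spec")
}

conv_block <- function(filters, with_1x1 = FALSE, with_dropout = FALSE,
                       dropout_rate = 0.25, kernel = c(3L, 3L)) {
  block <- rep(list(layer_spec("conv", kernel = kernel, filters = filters,
                               stride = c(1L, 1L), padding = "same",
                               activation = "relu")), 4)
  if (with_1x1) {
    block <- c(block, list(layer_spec("conv", kernel = c(1L, 1L),
                                      filters = filters,
                                      activation = "relu")))
  }
  block <- c(block, list(layer_spec("pool", kernel = c(2L, 2L),
                                    stride = c(2L, 2L))))
  if (with_dropout) {
    block <- c(block, list(layer_spec("dropout", rate = dropout_rate)))
  }
  block
}

#' Build an MKNet convolutional classifier specification
#'
#' MKNet is a family of small VGG-style convolutional networks for
#' 120 x 2400 monochrome FHR chart images. Variant A is one convolution
#' block -- four 3 x 3 stride-1 convolutions (jointly covering a 9 x 9
#' receptive field at a fraction of the cost of one 9 x 9 kernel) and one
#' 2 x 2 max-pooling layer -- followed by a fully connected layer and a
#' two-class softmax: seven counted layers. Variant B inserts a second
#' convolution block (12 layers), variant C a third (17 layers). Filters
#' per block default to 8, 16, 32. Optional extras (a 1 x 1 convolution
#' per block, extra dense layers fc2/fc3, dropout after each block) are
#' off by default so the canonical layer tallies hold.
#'
#' @param variant `"A"`, `"B"` or `"C"`.
#' @param with_1x1 add one 1 x 1 convolution per block.
#' @param with_fc2,with_fc3 add extra dense layers before the softmax.
#' @param with_dropout add a dropout layer after each block.
#' @param dropout_rate dropout fraction (default 0.25).
#' @param filters filters per block (recycled to 3).
#' @param fc_units widths of fc1/fc2/fc3.
#' @param input_shape image shape, `(rows, cols, channels)`.
#' @return a `model_spec`.
#' @export
#' @examples
#' count_layers(build_mknet("C"))  # 17
build_mknet <- function(variant = c("A", "B", "C"),
                        with_1x1 = FALSE, with_fc2 = FALSE,
                        with_fc3 = FALSE, with_dropout = FALSE,
                        dropout_rate = 0.25,
                        filters = c(8L, 16L, 32L),
                        fc_units = c(64L, 32L, 16L),
                        input_shape = c(120L, 2400L, 1L)) {
  variant <- match.arg(variant)
  n_blocks <- match(variant, c("A", "B", "C"))
  filters <- rep_len(filters, 3)
  layers <- list()
  for (b in seq_len(n_blocks)) {
    layers <- c(layers, conv_block(filters[b], with_1x1 = with_1x1,
                                   with_dropout = with_dropout,
                                   dropout_rate = dropout_rate))
  }
  layers <- c(layers, list(layer_spec("flatten")))
  layers <- c(layers, list(layer_spec("dense", units = fc_units[1],
                                      activation = "relu")))
  if (with_fc2) layers <- c(layers, list(layer_spec("dense",
                                                    units = fc_units[2],
                                                    activation = "relu")))
  if (with_fc3) layers <- c(layers, list(layer_spec("dense",
                                                    units = fc_units[3],
                                                    activation = "relu")))
  layers <- c(layers, list(layer_spec("softmax", units = 2L,
                                      activation = "softmax")))
  model_spec(paste0("MKNet-", variant), layers,
             input_shape = input_shape,
             options = list(with_1x1 = with_1x1, with_fc2 = with_fc2,
                            with_fc3 = with_fc3, with_dropout = with_dropout,
                            dropout_rate = dropout_rate))
}

#' Build the MKRNN recurrent classifier specification
#'
#' A single long short-term memory layer over the cleaned FHR time series
#' -- input shape `(timesteps, 1)`: one bpm observation per time step --
#' followed by a two-class softmax head. Trace values are scaled to
#' \[0, 1\] by `(v - 80) / 120` before training.
#'
#' @param units LSTM state width (default 64).
#' @param dropout,recurrent_dropout input / recurrent dropout fractions.
#' @param timesteps sequence length (default 2400).
#' @return a `model_spec`.
#' @export
build_mkrnn <- function(units = 64L, dropout = 0.2, recurrent_dropout = 0.2,
                        timesteps = 2400L) {
  if (units < 1) stop("`units` must be >= 1")
  layers <- list(
    layer_spec("lstm", units = as.integer(units), activation = "tanh",
               dropout = dropout, recurrent_dropout = recurrent_dropout),
    layer_spec("softmax", units = 2L, activation = "softmax")
  )
  model_spec("MKRNN", layers, input_shape = c(as.integer(timesteps), 1L),
             options = list(units = as.integer(units)))
}

#' Count the layers of a model specification
#'
#' Uses the tally convention under which MKNet-A/B/C count 7/12/17
#' layers: convolution, pooling, dense, LSTM and softmax layers are
#' counted; dropout and flatten are bookkeeping and are not.
#'
#' @param spec a `model_spec`.
#' @return integer layer count.
#' @export
count_layers <- function(spec) {
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  sum(kinds %in% c("conv", "pool", "dense", "softmax", "lstm"))
}

#' Effective receptive field of the convolutional stack
#'
#' Composes kernel sizes and strides of the spatial layers:
#' `rf <- rf + (k - 1) * jump; jump <- jump * stride`. Demonstrates the
#' kernel-substitution argument: four stacked 3 x 3 stride-1 convolutions
#' see a 9 x 9 input patch.
#'
#' @param spec a `model_spec`.
#' @param upto_layer last layer index to include; defaults to the last
#'   spatial (conv/pool) layer before any flatten/dense.
#' @return integer vector `(h, w)` in input pixels.
#' @export
#' @examples
#' receptive_field(build_mknet("A"), upto_layer = 4)  # c(9, 9)
receptive_field <- function(spec, upto_layer = NULL) {
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  if (is.null(upto_layer)) {
    # default: the contiguous spatial prefix (dropout passes through)
    ok <- kinds %in% c("conv", "pool", "dropout")
    if (!ok[1]) stop("no spatial layers in spec")
    upto_layer <- max(which(cumprod(ok) == 1))
  }
  rf <- c(1, 1); jump <- c(1, 1)
  for (l in spec$layers[seq_len(upto_layer)]) {
    if (l$kind == "dropout") next  # geometry-preserving
    if (!l$kind %in% c("conv", "pool")) {
      stop("non-spatial layer within the requested range")
    }
    k <- l$kernel
    s <- l$stride %||% c(1L, 1L)
    rf <- rf + (k - 1) * jump
    jump <- jump * s
  }
  as.integer(rf)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("%s: %d counted layers, input %s\n", x$name, count_layers(x),
              paste(x$input_shape, collapse = " x ")))
  kinds <- vapply(x$layers, `[[`, "", "kind")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    desc <- switch(l$kind,
      conv = sprintf("conv %dx%d, %d filters, stride %dx%d, %s",
                     l$kernel[1], l$kernel[2], l$filters,
                     l$stride[1], l$stride[2], l$activation),
      pool = sprintf("max-pool %dx%d", l$kernel[1], l$kernel[2]),
      dense = sprintf("dense %d, %s", l$units, l$activation),
      softmax = sprintf("softmax %d", l$units),
      dropout = sprintf("dropout %.2f", l$rate),
      lstm = sprintf("lstm %d units", l$units),
      flatten = "flatten")
    cat(sprintf("  %2d %s\n", i, desc))
  }
  invisible(x)
}

#' @export
summary.model_spec <- function(object, ...) {
  print(object)
  kinds <- vapply(object$layers, `[[`, "", "kind")
  cat(sprintf("conv %d | pool %d | dense+softmax %d | dropout %d\n",
              sum(kinds == "conv"), sum(kinds == "pool"),
              sum(kinds %in% c("dense", "softmax")),
              sum(kinds == "dropout")))
  invisible(object)
}

#' Training configuration
#'
#' @param epochs number of passes over the training set (>= 1; default 70).
#' @param batch_size minibatch size (default 32).
#' @param optimizer `"rmsprop"` or `"adagrad"`.
#' @param learning_rate step size (default 1e-3).
#' @param augmentation apply random horizontal shifts each epoch (images
#'   only).
#' @param augment_cfg an [augment_config()].
#' @param downscale integer `(row, col)` mean-pooling factors applied to
#'   image inputs before training; `(1, 1)` trains at native resolution.
#' @param subsample keep every `subsample`-th time step of sequence inputs
#'   (MKRNN); 1 keeps all 2400.
#' @param validation_fraction fraction of the training data held out for
#'   the per-epoch validation curve (0 disables).
#' @param seed integer seed controlling initialization, shuffling,
#'   dropout and augmentation.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 70, batch_size = 32,
                         optimizer = c("rmsprop", "adagrad"),
                         learning_rate = 1e-3,
                         augmentation = FALSE,
                         augment_cfg = augment_config(),
                         downscale = c(1L, 1L), subsample = 1L,
                         validation_fraction = 0, seed = 1L) {
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (batch_size < 1) stop("`batch_size` must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer),
                 learning_rate = learning_rate,
                 augmentation = augmentation,
                 augment_cfg = augment_cfg,
                 downscale = as.integer(rep_len(downscale, 2)),
                 subsample = as.integer(subsample),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}
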