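# Self-contained neural-network engine (base R).
#
# Activations are kept as 4-D arrays (h, w, c, n) for convolutional
# stacks, matrices (features x n) after flattening, and (T x n) matrices
# for single-feature sequences. Convolution is im2col + BLAS matmul;
# gradients are exact (verified against finite differences in the test
# suite). Only what MKNet/MKRNN need is implemented: 'same'-padded
# convolution, 2x2 max pooling, dense/softmax heads, inverted dropout,
# and a single LSTM layer trained by backpropagation through time.

as_dim4 <- function(x, d) { dim(x) <- d; x }

# ---- convolution ----------------------------------------------------------

# x: (h, w, cin, n); W: (kh, kw, cin, cout); 'same' padding, stride 1.
# Returns list(out, patches) where patches is the im2col matrix reused by
# the backward pass.
conv_forward <- function(x, W, b, stride = c(1L, 1L)) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  p0h <- (kh - 1L) %/% 2L; p0w <- (kw - 1L) %/% 2L
  xp <- array(0, c(h + kh - 1L, w + kw - 1L, cin, n))
  xp[p0h + seq_len(h), p0w + seq_len(w), , ] <- x
  hw <- h * w
  P <- matrix(0, kh * kw * cin, hw * n)
  r <- 0L
  for (ci in seq_len(cin)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    r <- r + 1L
    slab <- xp[dy + seq_len(h) - 1L, dx + seq_len(w) - 1L, ci, , drop = FALSE]
    P[r, ] <- slab
  }
  W2 <- matrix(W, kh * kw * cin, cout)  # (khkwcin) x cout
  out2 <- crossprod(W2, P) + b          # cout x (hw n)
  out <- aperm(array(out2, c(cout, h, w, n)), c(2, 3, 1, 4))
  if (any(stride != 1L)) {
    ri <- seq.int(1L, h, by = stride[1]); ci2 <- seq.int(1L, w, by = stride[2])
    out <- out[ri, ci2, , , drop = FALSE]
  }
  list(out = out, patches = P, in_dim = d, stride = stride)
}

conv_backward <- function(dout, cache, W) {
  d <- cache$in_dim; h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  kd <- dim(W); kh <- kd[1]; kw <- kd[2]; cout <- kd[4]
  st <- cache$stride
  if (any(st != 1L)) {  # zero-stuff back to the stride-1 grid
    full <- array(0, c(h, w, cout, n))
    ri <- seq.int(1L, h, by = st[1]); ci2 <- seq.int(1L, w, by = st[2])
    full[ri, ci2, , ] <- dout
    dout <- full
  }
  dout2 <- matrix(aperm(dout, c(3, 1, 2, 4)), cout, h * w * n)
  P <- cache$patches
  dW2 <- tcrossprod(P, dout2)                   # (khkwcin) x cout
  db <- rowSums(dout2)
  dP <- matrix(W, kh * kw * cin, cout) %*% dout2
  p0h <- (kh - 1L) %/% 2L; p0w <- (kw - 1L) %/% 2L
  dxp <- array(0, c(h + kh - 1L, w + kw - 1L, cin, n))
  r <- 0L
  for (ci in seq_len(cin)) for (dx in seq_len(kw)) for (dy in seq_len(kh)) {
    r <- r + 1L
    ys <- dy + seq_len(h) - 1L; xs <- dx + seq_len(w) - 1L
    dxp[ys, xs, ci, ] <- dxp[ys, xs, ci, , drop = FALSE] +
      array(dP[r, ], c(h, w, 1L, n))
  }
  dx <- dxp[p0h + seq_len(h), p0w + seq_len(w), , , drop = FALSE]
  list(dx = dx, dW = array(dW2, dim(W)), db = db)
}

# ---- 2x2 max pooling ------------------------------------------------------

pool_forward <- function(x) {
  d <- dim(x); h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  ro <- seq.int(1L, 2L * h2, 2L); co <- seq.int(1L, 2L * w2, 2L)
  a <- list(x[ro, co, , , drop = FALSE], x[ro + 1L, co, , , drop = FALSE],
            x[ro, co + 1L, , , drop = FALSE], x[ro + 1L, co + 1L, , , drop = FALSE])
  m <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  list(out = m, a = a, in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim; h2 <- dim(dout)[1]; w2 <- dim(dout)[2]
  ro <- seq.int(1L, 2L * h2, 2L); co <- seq.int(1L, 2L * w2, 2L)
  m <- cache$out %||% pmax(cache$a[[1]], cache$a[[2]], cache$a[[3]], cache$a[[4]])
  dx <- array(0, d)
  taken <- array(FALSE, dim(dout))
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    sel <- (cache$a[[k]] == m) & !taken
    taken <- taken | sel
    dy <- offs[[k]][1]; dxo <- offs[[k]][2]
    dx[ro + dy, co + dxo, , ] <- dx[ro + dy, co + dxo, , , drop = FALSE] +
      dout * sel
  }
  dx
}

# ---- dense / softmax / dropout -------------------------------------------

dense_forward <- function(x, W, b) W %*% x + b

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

dropout_mask <- function(dm, rate) {
  (matrix(runif(prod(dm)), dm[1], dm[2]) >= rate) / (1 - rate)
}

# ---- LSTM -----------------------------------------------------------------

sigm <- function(x) 1 / (1 + exp(-x))

# X: (T x n) single-feature sequences; returns final hidden state (u x n)
lstm_forward <- function(X, p, train = FALSE, dropout = 0,
                         recurrent_dropout = 0) {
  Tn <- nrow(X); n <- ncol(X); u <- ncol(p$Wh)
  h <- matrix(0, u, n); cc <- matrix(0, u, n)
  mx <- if (train && dropout > 0) dropout_mask(c(1L, n), dropout) else NULL
  mh <- if (train && recurrent_dropout > 0) {
    matrix(dropout_mask(c(u, n), recurrent_dropout), u, n)
  } else NULL
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(X[t, ], 1L, n)
    if (!is.null(mx)) xt <- xt * mx
    hin <- if (is.null(mh)) h else h * mh
    z <- p$Wx %*% xt + p$Wh %*% hin + p$b[, 1]
    i <- sigm(z[seq_len(u), , drop = FALSE])
    f <- sigm(z[u + seq_len(u), , drop = FALSE])
    o <- sigm(z[2L * u + seq_len(u), , drop = FALSE])
    g <- tanh(z[3L * u + seq_len(u), , drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    cache[[t]] <- list(xt = xt, hin = hin, h_prev = h_prev, i = i, f = f,
                       o = o, g = g, c_prev = c_prev, tc = tc)
  }
  list(h = h, cache = cache, mx = mx, mh = mh)
}

lstm_backward <- function(dh_last, fw, p) {
  cache <- fw$cache
  Tn <- length(cache); u <- ncol(p$Wh)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh <- dh_last; dc <- dh * 0
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    do <- dh * cc$tc
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- rbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + tcrossprod(dz, cc$xt)
    dWh <- dWh + tcrossprod(dz, cc$hin)
    db <- db + rowSums(dz)
    dh <- crossprod(p$Wh, dz)
    if (!is.null(fw$mh)) dh <- dh * fw$mh
    dc <- dc * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db)
}

# ---- network assembly -----------------------------------------------------

# Derive the runtime layer list (with concrete shapes and initialized
# parameters) from a model_spec and the actual input dimensions.
init_network <- function(spec, input_dim) {
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  is_seq <- any(kinds == "lstm")
  net <- list()
  if (is_seq) {
    feat <- 1L
    for (l in spec$layers) {
      rt <- l
      if (l$kind == "lstm") {
        u <- l$units
        rt$params <- list(
          Wx = matrix(rnorm(4L * u * feat, sd = sqrt(1 / max(feat, 1))), 4L * u, feat),
          Wh = matrix(rnorm(4L * u * u, sd = 1 / sqrt(u)), 4L * u, u),
          b = matrix(rep(c(0, 1, 0, 0), each = u), 4L * u, 1L)  # forget bias 1
        )
        feat <- u
      } else if (l$kind %in% c("dense", "softmax")) {
        rt$params <- list(
          W = matrix(rnorm(l$units * feat, sd = sqrt(2 / feat)), l$units, feat),
          b = matrix(0, l$units, 1L))
        feat <- l$units
      }
      net[[length(net) + 1L]] <- rt
    }
  } else {
    h <- input_dim[1]; w <- input_dim[2]; cin <- input_dim[3]
    feat <- NA_integer_
    for (l in spec$layers) {
      rt <- l
      if (l$kind == "conv") {
        kh <- l$kernel[1]; kw <- l$kernel[2]; f <- l$filters
        rt$params <- list(
          W = array(rnorm(kh * kw * cin * f, sd = sqrt(2 / (kh * kw * cin))),
                    c(kh, kw, cin, f)),
          b = rep(0, f))
        st <- l$stride %||% c(1L, 1L)
        h <- length(seq.int(1L, h, by = st[1]))
        w <- length(seq.int(1L, w, by = st[2]))
        cin <- f
      } else if (l$kind == "pool") {
        h <- h %/% 2L; w <- w %/% 2L
      } else if (l$kind == "flatten") {
        feat <- h * w * cin
      } else if (l$kind %in% c("dense", "softmax")) {
        rt$params <- list(
          W = matrix(rnorm(l$units * feat, sd = sqrt(2 / feat)), l$units, feat),
          b = matrix(0, l$units, 1L))
        feat <- l$units
      }
      net[[length(net) + 1L]] <- rt
    }
  }
  attr(net, "is_seq") <- is_seq
  net
}

# forward pass; returns probs (classes x n) and per-layer caches
net_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net))
  a <- x
  for (i in seq_along(net)) {
    l <- net[[i]]
    if (l$kind == "conv") {
      fw <- conv_forward(a, l$params$W, l$params$b, l$stride %||% c(1L, 1L))
      pre <- fw$out
      a <- pre * (pre > 0)  # relu
      caches[[i]] <- list(fw = fw, pre = pre)
    } else if (l$kind == "pool") {
      fw <- pool_forward(a)
      caches[[i]] <- fw
      a <- fw$out
    } else if (l$kind == "flatten") {
      caches[[i]] <- list(in_dim = dim(a))
      a <- matrix(a, prod(dim(a)[1:3]), dim(a)[4])
    } else if (l$kind == "dropout") {
      if (train && l$rate > 0) {
        m <- if (is.matrix(a)) dropout_mask(dim(a), l$rate) else
          array(dropout_mask(c(prod(dim(a)[1:3]), dim(a)[4]), l$rate), dim(a))
        a <- a * m
        caches[[i]] <- list(mask = m)
      }
    } else if (l$kind == "dense") {
      z <- dense_forward(a, l$params$W, l$params$b[, 1])
      caches[[i]] <- list(xin = a, pre = z)
      a <- z * (z > 0)
    } else if (l$kind == "softmax") {
      z <- dense_forward(a, l$params$W, l$params$b[, 1])
      caches[[i]] <- list(xin = a)
      a <- softmax_cols(z)
    } else if (l$kind == "lstm") {
      fw <- lstm_forward(a, l$params, train = train,
                         dropout = l$dropout %||% 0,
                         recurrent_dropout = l$recurrent_dropout %||% 0)
      caches[[i]] <- fw
      a <- fw$h
    }
  }
  list(probs = a, caches = caches)
}

# backward pass from cross-entropy on one-hot targets Y (classes x n);
# returns list of grads parallel to net
net_backward <- function(net, caches, probs, Y) {
  n <- ncol(Y)
  grads <- vector("list", length(net))
  delta <- (probs - Y) / n
  for (i in rev(seq_along(net))) {
    l <- net[[i]]
    if (l$kind == "softmax") {
      ca <- caches[[i]]
      grads[[i]] <- list(W = tcrossprod(delta, ca$xin),
                         b = matrix(rowSums(delta), ncol = 1L))
      delta <- crossprod(l$params$W, delta)
    } else if (l$kind == "dense") {
      ca <- caches[[i]]
      delta <- delta * (ca$pre > 0)
      grads[[i]] <- list(W = tcrossprod(delta, ca$xin),
                         b = matrix(rowSums(delta), ncol = 1L))
      delta <- crossprod(l$params$W, delta)
    } else if (l$kind == "dropout") {
      if (!is.null(caches[[i]])) delta <- delta * caches[[i]]$mask
    } else if (l$kind == "flatten") {
      delta <- array(delta, caches[[i]]$in_dim)
    } else if (l$kind == "pool") {
      delta <- pool_backward(delta, caches[[i]])
    } else if (l$kind == "conv") {
      ca <- caches[[i]]
      delta <- delta * (ca$pre > 0)
      bk <- conv_backward(delta, ca$fw, l$params$W)
      grads[[i]] <- list(W = bk$dW, b = bk$db)
      delta <- bk$dx
    } else if (l$kind == "lstm") {
      bk <- lstm_backward(delta, caches[[i]], l$params)
      grads[[i]] <- list(Wx = bk$dWx, Wh = bk$dWh, b = bk$db)
      delta <- NULL  # input gradient not needed (first layer)
    }
  }
  grads
}

cross_entropy <- function(probs, Y) {
  -mean(log(pmax(colSums(probs * Y), 1e-12)))
}

# ---- optimizers -----------------------------------------------------------

make_opt_state <- function(net) {
  lapply(net, function(l) {
    if (is.null(l$params)) NULL else lapply(l$params, function(p) p * 0)
  })
}

opt_update <- function(net, grads, state, optimizer, lr,
                       rho = 0.9, eps = 1e-8) {
  for (i in seq_along(net)) {
    if (is.null(grads[[i]])) next
    for (nm in names(net[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (optimizer == "rmsprop") {
        state[[i]][[nm]] <- rho * state[[i]][[nm]] + (1 - rho) * g^2
      } else {  # adagrad
        state[[i]][[nm]] <- state[[i]][[nm]] + g^2
      }
      net[[i]]$params[[nm]] <- net[[i]]$params[[nm]] -
        lr * g / (sqrt(state[[i]][[nm]]) + eps)
    }
  }
  list(net = net, state = state)
}
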