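# Independent reference implementations used as test oracles. These are
# deliberately naive (explicit loops, no vectorization) and share no code
# with the package internals.

# linear interpolation of zero runs, per-point neighbour search
oracle_interpolate <- function(v) {
  n <- length(v)
  nz <- which(v != 0)
  if (length(nz) == 0) stop("all zero")
  out <- v
  for (i in seq_len(n)) {
    if (v[i] != 0) next
    left <- nz[nz < i]
    right <- nz[nz > i]
    if (length(left) == 0) {
      out[i] <- v[min(right)]
    } else if (length(right) == 0) {
      out[i] <- v[max(left)]
    } else {
      l <- max(left); r <- min(right)
      out[i] <- v[l] + (v[r] - v[l]) * (i - l) / (r - l)
    }
  }
  out
}

# spike stabilization: same stated rule, naive stability scan
oracle_stabilize <- function(v, jump = 25, window = 5, sdiff = 10) {
  n <- length(v)
  is_stable_at <- function(v, jj) {
    if (jj + window > n) return(FALSE)
    for (t in 0:(window - 1)) {
      if (abs(v[jj + t + 1] - v[jj + t]) >= sdiff) return(FALSE)
    }
    TRUE
  }
  i <- 1
  while (i < n) {
    if (abs(v[i + 1] - v[i]) > jump) {
      j <- NA
      for (jj in (i + 1):n) {
        if (is_stable_at(v, jj)) { j <- jj; break }
      }
      if (is.na(j)) {
        for (t in (i + 1):n) v[t] <- v[i]
        break
      }
      if (j > i + 1) {
        for (t in (i + 1):(j - 1)) {
          v[t] <- v[i] + (v[j] - v[i]) * (t - i) / (j - i)
        }
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  v
}

# confusion-table tally by explicit counting
oracle_metrics <- function(y_true, y_pred) {
  acc <- sum(y_true == y_pred) / length(y_true)
  per <- list()
  for (cl in c(0, 1)) {
    tp <- fp <- fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) NaN else tp / (tp + fp)
    rec <- if (tp + fn == 0) NaN else tp / (tp + fn)
    f1 <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) {
      if (tp + fn == 0) NaN else 0
    } else 2 * prec * rec / (prec + rec)
    per[[as.character(cl)]] <- c(precision = prec, recall = rec, f1 = f1,
                                 support = tp + fn)
  }
  wavg <- function(field) {
    num <- den <- 0
    for (cl in c("0", "1")) {
      s <- per[[cl]][["support"]]
      v <- per[[cl]][[field]]
      if (s > 0 && !is.nan(v)) { num <- num + v * s; den <- den + s }
    }
    num / den
  }
  list(per = per, accuracy = acc, avg_precision = wavg("precision"),
       avg_recall = wavg("recall"), avg_f1 = wavg("f1"))
}

# AUC as the Mann-Whitney pair probability
oracle_auc <- function(y_true, scores) {
  pos <- scores[y_true == 1]
  neg <- scores[y_true == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# all value-vectors of length len over alphabet (matrix, one row per trace)
enumerate_traces <- function(len, alphabet) {
  m <- as.matrix(expand.grid(rep(list(alphabet), len)))
  dimnames(m) <- NULL
  m
}

# flat-trace image dataset separable by vertical position
make_toy_images <- function(n = 20, seed = 1, base0 = 140, base1 = 175) {
  set.seed(seed)
  imgs <- vector("list", n)
  y <- integer(n)
  for (i in seq_len(n)) {
    y[i] <- i %% 2L
    base <- if (y[i] == 0L) base0 else base1
    imgs[[i]] <- render_image(clip_range(rep(base, 2400) + rnorm(2400)))
  }
  list(x = imgs, y = y)
}

# two well-separated Gaussian feature clouds
make_gaussian_clouds <- function(n = 200, d = 4, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * d), n, d)
  x[y == 1, 1] <- x[y == 1, 1] + sep
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = y)
}
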