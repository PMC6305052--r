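#' Clip a trace to the chart band
#'
#' Rates below 80 bpm are raised to 80, above 200 lowered to 200, fixing
#' the vertical extent of the rendered chart.
#'
#' @param values bpm sequence with no missing values.
#' @return clipped sequence in \[80, 200\].
#' @export
clip_range <- function(values) pmin(200, pmax(80, values))

# bpm -> row index: 200 bpm -> row 0 (top), 80 bpm -> row 119 (bottom),
# linear with half-up rounding. Rows returned 0-based.
bpm_to_row <- function(v) round_half_up((200 - v) * 119 / 120)

row_to_bpm <- function(r) 200 - r * 120 / 119

#' Rasterize a clipped trace into a 120 x 2400 monochrome image
#'
#' Column `t` carries the curve sample `v[t]` at row
#' `round((200 - v[t]) * 119/120)` (half-up): 200 bpm maps to the top row
#' 0, 80 bpm to the bottom row 119. Consecutive samples are connected by
#' filling the vertical span between the previous and current row in the
#' current column, so the rendered curve is visually continuous and every
#' column contains at least one set pixel.
#'
#' @param values clipped bpm sequence of length 2400 (see [clip_range()]).
#' @param source_id identifier carried on the image.
#' @return object of class `"fhr_image"`: integer 0/1 matrix `pixels` of
#'   dimension 120 x 2400 plus `source_id`.
#' @export
render_image <- function(values, source_id = NA_character_) {
  if (length(values) != 2400) stop("trace must have exactly 2400 samples")
  if (any(values < 80) || any(values > 200)) {
    stop("values outside [80, 200]; run clip_range() first")
  }
  rows <- bpm_to_row(values)  # 0-based
  px <- matrix(0L, nrow = 120, ncol = 2400)
  px[rows[1] + 1L, 1L] <- 1L
  for (t in 2:2400) {
    lo <- min(rows[t - 1L], rows[t])
    hi <- max(rows[t - 1L], rows[t])
    px[(lo + 1L):(hi + 1L), t] <- 1L
  }
  structure(list(pixels = px, source_id = source_id), class = "fhr_image")
}

#' Recover the clipped trace from a rendered image
#'
#' Inverts [render_image()]: the first column holds a single pixel; in
#' each later column the curve row is the end of the vertical span
#' farther from (or equal to) the previous recovered row's opposite end,
#' i.e. the span endpoint that is not the carried-over previous row.
#' Recovery is exact to within half a row (about 0.5 bpm).
#'
#' @param image an `fhr_image`.
#' @return bpm sequence of length 2400.
#' @export
image_to_trace <- function(image) {
  px <- image$pixels
  n <- ncol(px)
  rows <- integer(n)
  set1 <- which(px[, 1] == 1L) - 1L
  rows[1] <- set1[1]
  for (t in 2:n) {
    set <- which(px[, t] == 1L) - 1L
    lo <- set[1]; hi <- set[length(set)]
    prev <- rows[t - 1L]
    rows[t] <- if (lo == prev) hi else if (hi == prev) lo else
      if (abs(lo - prev) > abs(hi - prev)) lo else hi
  }
  row_to_bpm(rows)
}

#' Horizontal-shift augmentation configuration
#'
#' The only label-preserving transformation used during training: a small
#' random horizontal translation. Flips and vertical shifts would change
#' the clinical meaning of the chart and are not offered.
#'
#' @param width_shift_fraction maximum shift as a fraction of image width,
#'   in \[0, 1\] (default 0.2).
#' @param fill_mode how vacated columns are filled; only
#'   `"nearest-column"` (replicate the nearest surviving column).
#' @param seed optional integer seed.
#' @return list of class `"augment_config"`.
#' @export
augment_config <- function(width_shift_fraction = 0.2,
                           fill_mode = "nearest-column", seed = NULL) {
  if (width_shift_fraction < 0 || width_shift_fraction > 1) {
    stop("`width_shift_fraction` must be in [0, 1]")
  }
  fill_mode <- match.arg(fill_mode, "nearest-column")
  structure(list(width_shift_fraction = width_shift_fraction,
                 fill_mode = fill_mode, seed = seed),
            class = "augment_config")
}

# shift a pixel matrix horizontally by d columns (+ = right), filling
# vacated columns by replicating the nearest surviving column
shift_columns <- function(px, d) {
  w <- ncol(px)
  d <- as.integer(d)
  if (d == 0L || abs(d) >= w) return(px)
  out <- px
  if (d > 0) {
    out[, (d + 1L):w] <- px[, 1L:(w - d)]
    out[, 1L:d] <- px[, 1L]
  } else {
    out[, 1L:(w + d)] <- px[, (1L - d):w]
    out[, (w + d + 1L):w] <- px[, w]
  }
  out
}

#' Randomly shift an image horizontally
#'
#' Draws a displacement uniformly from
#' `[-width_shift_fraction * width, +width_shift_fraction * width]`
#' (integer columns) and translates the image, replicating the nearest
#' surviving column into vacated columns so every column still shows the
#' curve. Shape is preserved; no flips, no vertical movement.
#'
#' @param image an `fhr_image` (or bare pixel matrix).
#' @param cfg an [augment_config()].
#' @return the shifted image, same class as the input; attribute `shift`
#'   records the displacement.
#' @export
shift_augment <- function(image, cfg = augment_config()) {
  px <- if (inherits(image, "fhr_image")) image$pixels else image
  with_seed(cfg$seed, {
    s <- floor(cfg$width_shift_fraction * ncol(px))
    d <- if (s == 0) 0L else sample(seq.int(-s, s), 1)
    out <- shift_columns(px, d)
    res <- if (inherits(image, "fhr_image")) {
      structure(list(pixels = out, source_id = image$source_id),
                class = "fhr_image")
    } else out
    attr(res, "shift") <- d
    res
  })
}

#' @export
print.fhr_image <- function(x, ...) {
  cat(sprintf("FHR image%s: %d x %d, %d set pixels\n",
              if (is.na(x$source_id)) "" else paste0(" [", x$source_id, "]"),
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Write an FHR image as a grayscale PNG
#'
#' Background is black (0), the curve white (255).
#'
#' @param image an `fhr_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels * 1.0, target = path)
  invisible(path)
}

# mean-pool a pixel matrix by integer factors (fh rows, fw cols); used to
# build reduced-resolution training inputs for scale-rehearsal runs
downscale_pixels <- function(px, fh, fw) {
  h <- nrow(px) %/% fh * fh
  w <- ncol(px) %/% fw * fw
  px <- px[seq_len(h), seq_len(w), drop = FALSE]
  pr <- colMeans(array(px, dim = c(fh, h %/% fh, w)))        # (h/fh) x w
  t(colMeans(array(t(pr), dim = c(fw, w %/% fw, h %/% fh)))) # (h/fh) x (w/fw)
}
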