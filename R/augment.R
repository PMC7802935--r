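#' Offline 5x rotation augmentation
#'
#' Expands a tile set five-fold: each tile contributes itself plus four copies
#' rotated by distinct random non-zero multiples of 45 degrees (the classic
#' pre-processing step applied before training rather than on the fly, so the
#' expensive interpolation happens once). Rotation is about the tile center
#' with bilinear interpolation; corners left undefined by the rotation are
#' filled with the tile's median (background) level. Input and target stacks
#' receive identical rotations.
#'
#' @param x 3-d array of input tiles `(H, W, N)`.
#' @param y Optional matched 3-d array of target tiles, rotated identically.
#' @param seed Integer seed controlling the per-tile angle draws.
#' @return A list with elements `x`, `y` (or `NULL`) of size `5 * N`, and
#'   `angles`, the `N x 5` matrix of applied angles (first column 0).
#' @export
augment_offline_rotations <- function(x, y = NULL, seed = 1L) {
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[3]
  if (n < 1) stop("tile stack is empty")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  angles <- t(vapply(seq_len(n), function(i)
    c(0, sample(seq(45, 315, by = 45), 4L)), numeric(5)))
  xo <- array(0, c(dim(x)[1:2], 5L * n))
  yo <- if (!is.null(y)) array(0, c(dim(y)[1:2], 5L * n)) else NULL
  for (i in seq_len(n)) {
    for (q in 1:5) {
      k <- (i - 1L) * 5L + q
      xo[, , k] <- rotate_tile(x[, , i], angles[i, q])
      if (!is.null(y)) yo[, , k] <- rotate_tile(y[, , i], angles[i, q])
    }
  }
  list(x = xo, y = yo, angles = angles)
}

# Rotate a matrix about its center, keeping dimensions; undefined corners are
# filled with the median level.
rotate_tile <- function(m, angle) {
  if (angle %% 360 == 0) return(m)
  bg <- stats::median(m)
  r <- EBImage::rotate(EBImage::Image(m), angle, bg.col = bg)
  r <- EBImage::imageData(r)
  center_crop(r, nrow(m), ncol(m))
}

center_crop <- function(m, h, w) {
  i0 <- floor((nrow(m) - h) / 2)
  j0 <- floor((ncol(m) - w) / 2)
  m[i0 + seq_len(h), j0 + seq_len(w), drop = FALSE]
}

# Pad a matrix by edge reflection up to (h, w), centered.
reflect_pad <- function(m, h, w) {
  ph <- h - nrow(m); pw <- w - ncol(m)
  if (ph < 0 || pw < 0) stop("target smaller than input")
  top <- floor(ph / 2); left <- floor(pw / 2)
  ridx <- reflect_index(nrow(m), top, ph - top)
  cidx <- reflect_index(ncol(m), left, pw - left)
  m[ridx, cidx, drop = FALSE]
}

reflect_index <- function(n, before, after) {
  vapply((1 - before):(n + after), function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    as.integer(i)
  }, integer(1))
}

#' Online flip/zoom augmentation
#'
#' Draws a random horizontal flip, vertical flip, and zoom factor (uniform in
#' `zoom_range`, i.e. up to 20 percent scale by default) and applies the
#' identical transform to the input tile and its target. Zoom resizes
#' bilinearly and then center-crops (zoom in) or reflect-pads (zoom out) back
#' to the original tile size.
#'
#' @param x Input tile (matrix).
#' @param y Optional target tile; receives the same transform.
#' @param zoom_range Length-2 numeric range for the zoom factor.
#' @param params Optional list `(flip_h, flip_v, zoom)` to replay a transform
#'   instead of drawing one.
#' @return List with `x`, `y` and `params` (the drawn transform, so a caller
#'   can verify both channels received the same one).
#' @export
augment_online <- function(x, y = NULL, zoom_range = c(0.8, 1.2),
                           params = NULL) {
  if (is.null(params))
    params <- list(flip_h = stats::runif(1) < 0.5,
                   flip_v = stats::runif(1) < 0.5,
                   zoom = stats::runif(1, zoom_range[1], zoom_range[2]))
  tf <- function(m) {
    if (params$flip_h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (params$flip_v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    zoom_tile(m, params$zoom)
  }
  list(x = tf(x), y = if (!is.null(y)) tf(y) else NULL, params = params)
}

zoom_tile <- function(m, s) {
  if (abs(s - 1) < 1e-12) return(m)
  h <- nrow(m); w <- ncol(m)
  nh <- max(2L, round(h * s)); nw <- max(2L, round(w * s))
  r <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = nh, h = nw))
  if (nh >= h && nw >= w) center_crop(r, h, w) else reflect_pad(r, h, w)
}
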