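#' Sliding-window stitching configuration
#'
#' Parameters of overlapping-patch inference over large images: `window`
#' (patch side, matching the network input), `stride` between patch origins
#' (default 64), and `border_exclude`, the margin of each predicted patch
#' discarded before averaging because predictions near patch borders are less
#' reliable (cells cut off at the edge). Margins are kept on sides where a
#' patch touches the image boundary so every output pixel retains coverage.
#'
#' @param window Patch side length in pixels (default 256).
#' @param stride Origin spacing in pixels, `1 <= stride <= window`; with a
#'   nonzero margin also `stride <= window - 2 * border_exclude`, so patch
#'   interiors always overlap and every output pixel keeps coverage.
#' @param border_exclude Margin width `b` in pixels, `0 <= b < window / 2`.
#' @return A `stitch_config` object.
#' @export
stitch_config <- function(window = 256L, stride = 64L, border_exclude = 16L) {
  window <- as.integer(window); stride <- as.integer(stride)
  border_exclude <- as.integer(border_exclude)
  if (stride < 1L || stride > window) stop("require 1 <= stride <= window")
  if (border_exclude < 0L || border_exclude >= window / 2)
    stop("require 0 <= border_exclude < window/2")
  if (stride > window - 2L * border_exclude)
    stop("require stride <= window - 2*border_exclude, ",
         "otherwise patch interiors leave coverage gaps")
  structure(list(window = window, stride = stride,
                 border_exclude = border_exclude, pad_mode = "reflect"),
            class = "stitch_config")
}

#' Patch origins of the sliding window
#'
#' Origins at multiples of `stride`, plus a final origin flush with each far
#' edge when the span is not a multiple of the stride, so windows never exceed
#' bounds and the whole image is covered.
#'
#' @param H,W Image dimensions (each `>= window`).
#' @param cfg A [stitch_config()].
#' @return Data frame of 0-based `(row, col)` origins.
#' @export
window_origins <- function(H, W, cfg = stitch_config()) {
  if (H < cfg$window || W < cfg$window)
    stop("image smaller than the window; reflect-pad upstream")
  ax <- function(n) {
    o <- seq(0L, n - cfg$window, by = cfg$stride)
    if (o[length(o)] != n - cfg$window) o <- c(o, n - cfg$window)
    o
  }
  expand.grid(row = ax(H), col = ax(W))
}

# A patch-level prediction function (counts in -> counts out) for either a
# fitted model or a user-supplied oracle function.
patch_predictor <- function(model) {
  if (inherits(model, "frm_model")) {
    function(patches) {  # (w, w, N) array, counts
      z <- normalize_tiles(patches, model$norm_in)
      denormalize(unet_predict_tiles(model$net, z), model$norm_out)
    }
  } else if (is.function(model)) {
    function(patches) {
      out <- patches
      for (q in seq_len(dim(patches)[3])) out[, , q] <- model(patches[, , q])
      out
    }
  } else stop("model must be an frm_model or a function")
}

#' Sliding-window prediction over a large image
#'
#' Applies the model to overlapping `window`-sized patches of the image at the
#' configured stride and averages (unweighted) all contributions at each
#' pixel. Each patch contributes only its interior -- margins of width
#' `border_exclude` are discarded, except on sides where the patch touches the
#' image boundary. Images smaller than the window are reflect-padded,
#' predicted, and cropped back. The output has exactly the input dimensions.
#'
#' @param model An `frm_model`, or a plain function `matrix -> matrix`
#'   (useful as an analytic oracle).
#' @param image Numeric matrix in counts.
#' @param cfg A [stitch_config()].
#' @param clamp Clamp the output to `[0, 65535]` counts.
#' @param return_coverage Also return the per-pixel contribution count.
#' @return The predicted image (matrix), or a list `(prediction, coverage)`.
#' @export
sliding_window_predict <- function(model, image, cfg = stitch_config(),
                                   clamp = TRUE, return_coverage = FALSE) {
  H0 <- nrow(image); W0 <- ncol(image)
  if (H0 < cfg$window || W0 < cfg$window) {
    padded <- reflect_pad(image, max(H0, cfg$window), max(W0, cfg$window))
    out <- sliding_window_predict(model, padded, cfg, clamp = clamp,
                                  return_coverage = return_coverage)
    crop <- function(m) {
      i0 <- floor((nrow(m) - H0) / 2); j0 <- floor((ncol(m) - W0) / 2)
      m[i0 + seq_len(H0), j0 + seq_len(W0), drop = FALSE]
    }
    if (return_coverage)
      return(list(prediction = crop(out$prediction),
                  coverage = crop(out$coverage)))
    return(crop(out))
  }
  orig <- window_origins(H0, W0, cfg)
  w <- cfg$window; b <- cfg$border_exclude
  pred_fun <- patch_predictor(model)
  acc <- matrix(0, H0, W0); cov <- matrix(0, H0, W0)
  chunk <- 16L
  for (start in seq(1L, nrow(orig), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(orig))
    patches <- array(0, c(w, w, length(rows)))
    for (q in seq_along(rows))
      patches[, , q] <- image[orig$row[rows[q]] + seq_len(w),
                              orig$col[rows[q]] + seq_len(w)]
    pp <- pred_fun(patches)
    if (any(!is.finite(pp)))
      stop("non-finite model output at patch origin (",
           orig$row[rows[which(apply(!is.finite(pp), 3, any))[1]]], ", ",
           orig$col[rows[which(apply(!is.finite(pp), 3, any))[1]]], ")")
    for (q in seq_along(rows)) {
      r0 <- orig$row[rows[q]]; c0 <- orig$col[rows[q]]
      top <- if (r0 == 0L) 0L else b
      bot <- if (r0 + w == H0) 0L else b
      lef <- if (c0 == 0L) 0L else b
      rig <- if (c0 + w == W0) 0L else b
      ri <- (1L + top):(w - bot); ci <- (1L + lef):(w - rig)
      acc[r0 + ri, c0 + ci] <- acc[r0 + ri, c0 + ci] + pp[ri, ci, q]
      cov[r0 + ri, c0 + ci] <- cov[r0 + ri, c0 + ci] + 1
    }
  }
  if (min(cov) < 1) stop("internal error: uncovered output pixel")
  out <- acc / cov
  if (clamp) out <- pmin(pmax(out, 0), 65535)
  if (return_coverage) list(prediction = out, coverage = cov) else out
}

#' Frame-by-frame timelapse prediction
#'
#' Applies [sliding_window_predict()] independently to every frame of a
#' multi-page stack, preserving frame count and order.
#'
#' @param model An `frm_model` or oracle function.
#' @param stack List of matrices (frames), all of identical dimensions.
#' @param cfg A [stitch_config()].
#' @param clamp Clamp output to `[0, 65535]`.
#' @return List of predicted frames.
#' @export
predict_timelapse <- function(model, stack, cfg = stitch_config(),
                              clamp = TRUE) {
  stopifnot(is.list(stack), length(stack) >= 1)
  d1 <- dim(stack[[1]])
  for (f in stack) if (!identical(dim(f), d1))
    stop("mixed frame sizes in the stack")
  lapply(stack, function(f)
    sliding_window_predict(model, f, cfg, clamp = clamp))
}

#' Cross-platform pixel-size correction
#'
#' Rescales an image so its effective sampling (micrometers per pixel)
#' matches a reference optical system, the pre-processing step that lets a
#' network trained on one microscope be applied to images from another.
#' When objective magnifications are supplied, effective um/px = camera pixel
#' pitch / magnification; otherwise the given um/px values are used as-is.
#' The scale factor is `src_effective / ref_effective`; output dimensions are
#' `round(input * factor)`, bilinear interpolation.
#'
#' @param image Numeric matrix.
#' @param src_um_per_px,ref_um_per_px Camera pixel sizes (um/px) of the
#'   source and reference systems.
#' @param src_magnification,ref_magnification Optional objective
#'   magnifications of the two systems.
#' @return The rescaled image, with attributes `factor` and `native_dim`
#'   (the original dimensions, for the inverse mapping).
#' @export
rescale_to_reference <- function(image, src_um_per_px, ref_um_per_px,
                                 src_magnification = NULL,
                                 ref_magnification = NULL) {
  if (src_um_per_px <= 0 || ref_um_per_px <= 0)
    stop("pixel sizes must be positive")
  src_eff <- if (is.null(src_magnification)) src_um_per_px
             else src_um_per_px / src_magnification
  ref_eff <- if (is.null(ref_magnification)) ref_um_per_px
             else ref_um_per_px / ref_magnification
  factor <- src_eff / ref_eff
  nd <- dim(image)
  if (abs(factor - 1) < 1e-12) {
    out <- image
  } else {
    out <- EBImage::imageData(EBImage::resize(
      EBImage::Image(image), w = round(nd[1] * factor),
      h = round(nd[2] * factor)))
  }
  structure(out, factor = factor, native_dim = nd)
}

#' @rdname rescale_to_reference
#' @param native_dim Target `(rows, cols)` to restore (the source image's
#'   native geometry).
#' @export
rescale_to_native <- function(image, native_dim) {
  if (identical(dim(image), as.integer(native_dim))) return(image)
  EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                     w = native_dim[1], h = native_dim[2]))
}
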