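#' Pearson's correlation coefficient between two intensity vectors
#'
#' The standard colocalization statistic
#' `sum((R - Rbar)(G - Gbar)) / sqrt(sum((R - Rbar)^2) sum((G - Gbar)^2))`,
#' symmetric in its arguments and invariant to positive affine rescaling of
#' either one.
#'
#' @param r,g Numeric vectors/matrices of equal length (>= 2), e.g. a ground
#'   truth image and its reconstruction.
#' @return A value in `[-1, 1]`.
#' @export
pcc <- function(r, g) {
  r <- as.numeric(r); g <- as.numeric(g)
  if (length(r) != length(g)) stop("length mismatch")
  if (length(r) < 2) stop("need at least 2 pixels")
  a <- r - mean(r); b <- g - mean(g)
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0)
    stop("PCC undefined for a constant vector")
  sum(a * b) / sqrt(na2 * nb2)
}

#' Evaluation configuration
#'
#' @param feature_threshold Intensity threshold (counts) separating feature
#'   signal from background in the ground truth. `NULL` selects it
#'   automatically by Otsu's method on the pooled ground-truth histogram.
#' @param min_feature_pixels Number of ground-truth pixels above threshold
#'   needed to call an image feature-positive (default 64, about 0.1 percent
#'   of a 256x256 tile).
#' @param outlier_rule `"scaled_mad_3"` (drop beyond 3 scaled median absolute
#'   deviations) or `"none"`.
#' @param bins Cytofluorogram bin count per axis.
#' @param bit_depth Bit depth defining the intensity range.
#' @return A `metric_config` object.
#' @export
metric_config <- function(feature_threshold = NULL, min_feature_pixels = 64L,
                          outlier_rule = c("scaled_mad_3", "none"),
                          bins = 64L, bit_depth = 16L) {
  outlier_rule <- match.arg(outlier_rule)
  if (min_feature_pixels < 1) stop("min_feature_pixels must be >= 1")
  if (!is.null(feature_threshold) &&
      (feature_threshold < 0 || feature_threshold > 2^bit_depth - 1))
    stop("feature_threshold outside the bit-depth range")
  structure(list(feature_threshold = feature_threshold,
                 min_feature_pixels = as.integer(min_feature_pixels),
                 outlier_rule = outlier_rule, bins = as.integer(bins),
                 bit_depth = as.integer(bit_depth)),
            class = "metric_config")
}

# Accept a (H,W,N) array or list of matrices; return list of matrices.
as_image_list <- function(x) {
  if (is.list(x)) x
  else if (length(dim(x)) == 3)
    lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  else list(x)
}

resolve_tau <- function(truth_list, cfg) {
  if (!is.null(cfg$feature_threshold)) return(cfg$feature_threshold)
  maxv <- 2^cfg$bit_depth - 1
  pooled <- unlist(lapply(truth_list, as.numeric), use.names = FALSE)
  as.numeric(EBImage::otsu(EBImage::Image(matrix(pooled / maxv)),
                           range = c(0, 1), levels = 256L)) * maxv
}

#' Feature-positive / background partition of a test set
#'
#' An image is feature-positive when at least `min_feature_pixels` of its
#' ground-truth pixels exceed the intensity threshold; the rest are
#' background-only. This is the filter behind the corrected accuracy score P,
#' which prevents background-only tiles (whose reconstructions are
#' pseudo-random noise) from dragging down the dataset-level score.
#'
#' @param truth Ground-truth images: `(H, W, N)` array or list of matrices.
#' @param cfg A [metric_config()].
#' @return List with logical vector `positive`, the threshold `tau` used, and
#'   indices `positive_idx` / `background_idx`.
#' @export
filter_feature_positive <- function(truth, cfg = metric_config()) {
  tl <- as_image_list(truth)
  tau <- resolve_tau(tl, cfg)
  pos <- vapply(tl, function(m) sum(m > tau) >= cfg$min_feature_pixels,
                logical(1))
  list(positive = pos, tau = tau,
       positive_idx = which(pos), background_idx = which(!pos))
}

#' Scaled-MAD outlier removal
#'
#' Drops values farther than 3 scaled median absolute deviations
#' (scale constant 1.4826) from the median, preserving order -- the default
#' behaviour of the common `rmoutliers`-style median rule. When the MAD is 0,
#' only values different from the median are removed.
#'
#' @param values Non-empty numeric vector.
#' @param rule `"scaled_mad_3"` or `"none"` (identity).
#' @return The retained values, with attribute `removed` (indices dropped).
#' @export
remove_outliers <- function(values, rule = c("scaled_mad_3", "none")) {
  rule <- match.arg(rule)
  if (length(values) == 0) stop("empty input")
  if (rule == "none") return(structure(values, removed = integer()))
  med <- stats::median(values)
  smad <- stats::mad(values, constant = 1.4826)
  keep <- abs(values - med) <= 3 * smad
  structure(values[keep], removed = which(!keep))
}

#' Corrected accuracy score P
#'
#' Per-image Pearson correlation between ground truth and prediction,
#' restricted to the feature-positive subset of the test set, with scaled-MAD
#' outlier removal, summarized as the accuracy score P. Images where the PCC
#' is undefined (constant truth or prediction) are skipped and counted.
#'
#' @param truth,pred Matched image sets (`(H, W, N)` arrays or lists).
#' @param cfg A [metric_config()].
#' @return A `metric_report` list: `per_image` (data frame `tile_id`, `pcc`,
#'   `is_feature_positive`, `is_outlier`, `skipped`), `P` (mean, median,
#'   quartiles, n over retained feature-positive images), `tau`,
#'   `raw` (the same summary over every scoreable image, i.e. the
#'   uncorrected whole-set PCC), and `n_skipped`.
#' @export
accuracy_score_P <- function(truth, pred, cfg = metric_config()) {
  tl <- as_image_list(truth); pl <- as_image_list(pred)
  stopifnot(length(tl) == length(pl))
  filt <- filter_feature_positive(tl, cfg)
  n <- length(tl)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ok <- stats::sd(tl[[i]]) > 0 && stats::sd(pl[[i]]) > 0
    if (ok) vals[i] <- pcc(tl[[i]], pl[[i]])
  }
  per_image <- data.frame(tile_id = seq_len(n), pcc = vals,
                          is_feature_positive = filt$positive,
                          is_outlier = FALSE, skipped = is.na(vals))
  pos_vals <- vals[filt$positive & !is.na(vals)]
  if (length(pos_vals) == 0) stop("empty subset: no feature-positive images")
  kept <- remove_outliers(pos_vals, cfg$outlier_rule)
  rm_idx <- attr(kept, "removed")
  pos_ids <- per_image$tile_id[filt$positive & !is.na(vals)]
  per_image$is_outlier[per_image$tile_id %in% pos_ids[rm_idx]] <- TRUE
  summ <- function(v) list(mean = mean(v), median = stats::median(v),
                           q1 = unname(stats::quantile(v, 0.25)),
                           q3 = unname(stats::quantile(v, 0.75)),
                           n = length(v))
  structure(list(per_image = per_image, P = summ(as.numeric(kept)),
                 raw = summ(vals[!is.na(vals)]), tau = filt$tau,
                 n_skipped = sum(is.na(vals))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "Accuracy score P = %.4f (median %.4f, n = %d feature-positive images)\n",
    x$P$mean, x$P$median, x$P$n))
  cat(sprintf("Raw whole-set PCC mean = %.4f (n = %d; tau = %.1f counts)\n",
              x$raw$mean, x$raw$n, x$tau))
  if (x$n_skipped > 0)
    cat(x$n_skipped, "image(s) skipped (undefined PCC)\n")
  invisible(x)
}

#' Segmentation PCC on suprathreshold pixels
#'
#' For each image pair, builds the mask of ground-truth pixels exceeding the
#' threshold and reports the PCC restricted to those pixels -- a
#' foreground-only agreement score. Images whose mask holds fewer than 2
#' pixels or constant masked values are skipped (counted in the summary).
#'
#' @inheritParams accuracy_score_P
#' @return List: `per_image` (data frame `tile_id`, `pcc`, `mask_pixels`,
#'   `skipped`), `summary` (mean/median/n), `tau`, `n_skipped`.
#' @export
segmentation_pcc <- function(truth, pred, cfg = metric_config()) {
  tl <- as_image_list(truth); pl <- as_image_list(pred)
  stopifnot(length(tl) == length(pl))
  tau <- resolve_tau(tl, cfg)
  n <- length(tl)
  vals <- rep(NA_real_, n); npx <- integer(n)
  for (i in seq_len(n)) {
    mask <- tl[[i]] > tau
    npx[i] <- sum(mask)
    if (npx[i] >= 2) {
      rr <- tl[[i]][mask]; gg <- pl[[i]][mask]
      if (stats::sd(rr) > 0 && stats::sd(gg) > 0) vals[i] <- pcc(rr, gg)
    }
  }
  ok <- !is.na(vals)
  list(per_image = data.frame(tile_id = seq_len(n), pcc = vals,
                              mask_pixels = npx, skipped = !ok),
       summary = if (any(ok)) list(mean = mean(vals[ok]),
                                   median = stats::median(vals[ok]),
                                   n = sum(ok))
                 else list(mean = NA_real_, median = NA_real_, n = 0L),
       tau = tau, n_skipped = sum(!ok))
}

#' Cytofluorogram (2-d intensity histogram)
#'
#' Tallies every spatially corresponding (ground truth, prediction) pixel
#' pair into a `bins x bins` count matrix over the native bit-depth range;
#' a perfect prediction puts all mass on the diagonal. Optionally also
#' returns a zoomed tally restricted to feature-region pixels
#' (ground truth > `tau`).
#'
#' @inheritParams accuracy_score_P
#' @param zoom_tau Optional threshold for the feature-region zoom panel.
#' @return List: `counts` (bins x bins matrix, truth rows x prediction
#'   columns), `breaks`, `n_pixels`, and optionally `zoom` (same structure
#'   over truth > `zoom_tau`).
#' @export
cytofluorogram <- function(truth, pred, cfg = metric_config(),
                           zoom_tau = NULL) {
  tl <- as_image_list(truth); pl <- as_image_list(pred)
  stopifnot(length(tl) == length(pl))
  maxv <- 2^cfg$bit_depth - 1
  breaks <- seq(0, maxv, length.out = cfg$bins + 1L)
  tv <- pmin(pmax(unlist(lapply(tl, as.numeric)), 0), maxv)
  pv <- pmin(pmax(unlist(lapply(pl, as.numeric)), 0), maxv)
  bin <- function(v) pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                          cfg$bins)
  counts <- matrix(0L, cfg$bins, cfg$bins)
  tb <- bin(tv); pb <- bin(pv)
  tab <- table(factor(tb, levels = seq_len(cfg$bins)),
               factor(pb, levels = seq_len(cfg$bins)))
  counts <- matrix(as.integer(tab), cfg$bins, cfg$bins)
  out <- list(counts = counts, breaks = breaks, n_pixels = length(tv))
  if (!is.null(zoom_tau)) {
    sel <- tv > zoom_tau
    ztab <- table(factor(tb[sel], levels = seq_len(cfg$bins)),
                  factor(pb[sel], levels = seq_len(cfg$bins)))
    out$zoom <- list(counts = matrix(as.integer(ztab), cfg$bins, cfg$bins),
                     tau = zoom_tau, n_pixels = sum(sel))
  }
  out
}
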