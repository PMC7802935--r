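#' Nuclei segmentation configuration
#'
#' @param blur_sigma Gaussian pre-blur sigma in pixels (default 2).
#' @param threshold `"otsu"` for automatic thresholding, or a fixed intensity
#'   in counts.
#' @param min_area,max_area Size-exclusion bounds in px^2 (clusters and debris
#'   are rejected outside this range).
#' @param watershed Split touching objects with a distance-transform
#'   watershed (default on).
#' @return A `seg_config` object.
#' @export
seg_config <- function(blur_sigma = 2.0, threshold = "otsu",
                       min_area = 20L, max_area = Inf, watershed = TRUE) {
  if (min_area >= max_area) stop("min_area must be < max_area")
  structure(list(blur_sigma = blur_sigma, threshold = threshold,
                 min_area = min_area, max_area = max_area,
                 watershed = watershed),
            class = "seg_config")
}

#' Segment nuclei
#'
#' The standard pipeline: Gaussian blur, (auto-)thresholding,
#' distance-transform watershed to split touching nuclei, connected
#' components, and size exclusion. Deterministic for fixed input and
#' configuration. Applied identically to ground-truth and predicted
#' fluorescence so their readouts are comparable.
#'
#' @param image Grayscale intensity matrix (counts).
#' @param cfg A [seg_config()].
#' @param um_per_px Physical pixel size recorded on the result.
#' @return A `label_map`: integer `labels` matrix (0 = background, objects
#'   numbered consecutively from 1) and an `objects` data frame
#'   (`label`, `centroid_row`, `centroid_col`, `area` in px^2).
#' @export
segment_nuclei <- function(image, cfg = seg_config(), um_per_px = 1) {
  maxv <- max(image, 1)
  img01 <- image / maxv
  blurred <- if (cfg$blur_sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(img01),
                                      sigma = cfg$blur_sigma))
  else img01
  thr <- if (identical(cfg$threshold, "otsu"))
    as.numeric(EBImage::otsu(EBImage::Image(blurred), range = c(0, 1),
                             levels = 256L))
  else cfg$threshold / maxv
  mask <- blurred > thr
  if (!any(mask)) return(label_map(matrix(0L, nrow(image), ncol(image)),
                                   um_per_px))
  labels <- if (cfg$watershed) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  }
  label_map(size_filter(labels, cfg$min_area, cfg$max_area), um_per_px)
}

# Drop objects outside [min_area, max_area] and relabel consecutively.
size_filter <- function(labels, min_area, max_area) {
  if (max(labels) == 0) return(matrix(0L, nrow(labels), ncol(labels)))
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(areas >= min_area & areas <= max_area)
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- remap[labels[nz]]
  out
}

#' @rdname segment_nuclei
#' @param labels Integer label matrix (0 background, consecutive positive
#'   object labels).
#' @export
label_map <- function(labels, um_per_px = 1) {
  storage.mode(labels) <- "integer"
  nlab <- max(labels, 0L)
  if (nlab > 0) {
    idx <- which(labels > 0)
    lab <- labels[idx]
    rows <- (idx - 1L) %% nrow(labels) + 1L
    cols <- (idx - 1L) %/% nrow(labels) + 1L
    objects <- data.frame(
      label = seq_len(nlab),
      centroid_row = as.numeric(rowsum(rows, lab) / tabulate(lab, nlab)),
      centroid_col = as.numeric(rowsum(cols, lab) / tabulate(lab, nlab)),
      area = tabulate(lab, nlab))
  } else {
    objects <- data.frame(label = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area = integer())
  }
  structure(list(labels = labels, objects = objects, um_per_px = um_per_px),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("Label map: ", nrow(x$objects), " object(s) in ",
      nrow(x$labels), "x", ncol(x$labels), " field (",
      x$um_per_px, " um/px)\n", sep = "")
  invisible(x)
}

#' Object-count error between two segmentations
#'
#' `100 * |n_pred - n_gt| / n_gt`, the percentage disagreement in object
#' counts between a ground-truth and a predicted field of view.
#'
#' @param gt,pred `label_map`s from the same field of view.
#' @return Percent error (nonnegative).
#' @export
count_error <- function(gt, pred) {
  n_gt <- nrow(gt$objects); n_pred <- nrow(pred$objects)
  if (n_gt == 0) stop("count error undefined: ground truth has no objects")
  100 * abs(n_pred - n_gt) / n_gt
}

#' Centroid displacements between matched objects
#'
#' Matches ground-truth and predicted centroids one-to-one by a greedy
#' globally-nearest-first rule with a distance cap (treating the two label
#' maps as consecutive frames of a video, as in two-frame particle linking)
#' and returns the Euclidean displacement of every matched pair in
#' micrometers. Unmatched objects on either side are counted.
#'
#' @param gt,pred `label_map`s with `um_per_px` set.
#' @param max_link_dist Maximum linking distance in pixels (default 15).
#' @param outlier_rule Rule applied by the summary (see [remove_outliers()]).
#' @return List: `displacements_um`, `unmatched_gt`, `unmatched_pred`,
#'   `summary` (mean/median/n after outlier removal).
#' @export
centroid_displacements <- function(gt, pred, max_link_dist = 15,
                                   outlier_rule = "scaled_mad_3") {
  a <- gt$objects; b <- pred$objects
  if (nrow(a) == 0 || nrow(b) == 0)
    return(list(displacements_um = numeric(), unmatched_gt = nrow(a),
                unmatched_pred = nrow(b),
                summary = list(mean = NA_real_, median = NA_real_, n = 0L)))
  d <- sqrt(outer(a$centroid_row, b$centroid_row, "-")^2 +
            outer(a$centroid_col, b$centroid_col, "-")^2)
  cand <- which(d <= max_link_dist, arr.ind = TRUE)
  ord <- order(d[cand])
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  disp <- numeric()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    disp <- c(disp, d[i, j] * gt$um_per_px)
  }
  kept <- if (length(disp)) remove_outliers(disp, outlier_rule) else disp
  list(displacements_um = disp,
       unmatched_gt = sum(!used_a), unmatched_pred = sum(!used_b),
       summary = list(mean = if (length(kept)) mean(kept) else NA_real_,
                      median = if (length(kept)) stats::median(kept) else NA_real_,
                      n = length(kept)))
}

#' Nuclear area distribution
#'
#' Per-object areas in px^2 and um^2 with scaled-MAD outlier removal and the
#' usual distribution summary for violin plotting.
#'
#' @param map A `label_map`.
#' @param outlier_rule See [remove_outliers()].
#' @return List: `areas_px2`, `areas_um2` (retained values), `summary`
#'   (mean/median/q1/q3/n on px^2), `n_removed`.
#' @export
nuclear_area_stats <- function(map, outlier_rule = "scaled_mad_3") {
  areas <- map$objects$area
  if (length(areas) == 0)
    return(list(areas_px2 = numeric(), areas_um2 = numeric(),
                summary = list(mean = NA_real_, median = NA_real_,
                               q1 = NA_real_, q3 = NA_real_, n = 0L),
                n_removed = 0L))
  kept <- remove_outliers(areas, outlier_rule)
  v <- as.numeric(kept)
  list(areas_px2 = v, areas_um2 = v * map$um_per_px^2,
       summary = list(mean = mean(v), median = stats::median(v),
                      q1 = unname(stats::quantile(v, 0.25)),
                      q3 = unname(stats::quantile(v, 0.75)), n = length(v)),
       n_removed = length(attr(kept, "removed")))
}

#' Cell areas from a junction image
#'
#' Reproduces the junction-based area pipeline: normalize the image to the
#' 16-bit histogram, threshold at a fraction of the dynamic range (~30
#' percent cut-off), skeletonize the binary junction network to 1-px cellular
#' outlines, close them with a single 3x3 dilation, invert, and measure
#' 4-connected regions (so 8-connected skeleton lines cannot leak between
#' cells). Border-touching regions are excluded by default, as in standard
#' particle analysis.
#'
#' @param junction_image Intensity matrix (counts).
#' @param threshold_frac Fraction of the dynamic range used as the threshold.
#' @param exclude_border Drop regions touching the frame edge.
#' @param min_area Minimum region area in px^2 (default 1, i.e. keep all).
#' @return List: `areas` data frame (`region`, `area` px^2), `labels` matrix,
#'   `boundary_pixels` (count of skeleton+dilation pixels), `n_excluded`
#'   (border regions dropped).
#' @export
cell_areas_from_junctions <- function(junction_image, threshold_frac = 0.30,
                                      exclude_border = TRUE, min_area = 1L) {
  img <- normalize_bit_depth(junction_image, 16, 16, stretch = TRUE)
  tau <- threshold_frac * 65535
  mask <- matrix(as.integer(img >= tau), nrow(img), ncol(img))
  skel <- .thin_binary(mask)
  closed <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(skel), EBImage::makeBrush(3, shape = "box"))) > 0
  interior <- matrix(as.integer(!closed), nrow(img), ncol(img))
  labels <- .label4(interior)
  n_excluded <- 0L
  if (exclude_border && max(labels) > 0) {
    border_labs <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
    border_labs <- border_labs[border_labs > 0]
    n_excluded <- length(border_labs)
    labels[labels %in% border_labs] <- 0L
  }
  labels <- size_filter(labels, min_area, Inf)
  nlab <- max(labels)
  areas <- if (nlab > 0)
    data.frame(region = seq_len(nlab),
               area = tabulate(labels[labels > 0], nlab))
  else data.frame(region = integer(), area = integer())
  list(areas = areas, labels = labels, boundary_pixels = sum(closed),
       n_excluded = n_excluded)
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at approximately unit-spaced
#' points along the segment from `p0` to `p1`, endpoints inclusive -- the
#' line-ROI intensity export used to compare ground-truth and reconstructed
#' junction cross-sections.
#'
#' @param image Intensity matrix.
#' @param p0,p1 Endpoints `(row, col)`, 1-based, inside the image.
#' @return Numeric vector of sampled intensities.
#' @export
line_profile <- function(image, p0, p1) {
  H <- nrow(image); W <- ncol(image)
  for (p in list(p0, p1))
    if (p[1] < 1 || p[1] > H || p[2] < 1 || p[2] > W)
      stop("endpoint out of bounds")
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, round(len) + 1L)
  t <- seq(0, 1, length.out = n)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  bilinear_sample(image, rr, cc)
}

bilinear_sample <- function(image, rr, cc) {
  H <- nrow(image); W <- ncol(image)
  r0 <- pmin(pmax(floor(rr), 1L), H - 1L); c0 <- pmin(pmax(floor(cc), 1L), W - 1L)
  fr <- rr - r0; fc <- cc - c0
  i00 <- image[cbind(r0, c0)];     i10 <- image[cbind(r0 + 1L, c0)]
  i01 <- image[cbind(r0, c0 + 1L)]; i11 <- image[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}
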