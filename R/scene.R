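#' Synthetic scene specification
#'
#' Parameters of the deterministic generator of paired transmitted-light-like
#' and fluorescence-like images used to exercise the whole framework without
#' microscopy data. A scene is a field of cells: seed points define a Voronoi
#' tessellation whose edges stand in for cell-cell junctions, each cell
#' carries an elliptical nucleus, and cortical bands plus sparse interior
#' fibers stand in for actin.
#'
#' @param field_size `(H, W)` in pixels.
#' @param n_cells Number of cells to place.
#' @param layout `"jittered_grid"` (regular lattice with uniform jitter) or
#'   `"uniform_random"` (rejection-sampled with a minimum spacing).
#' @param nucleus_axes_range `(min, max)` of the ellipse semi-axes in px.
#' @param junction_width Gaussian cross-section sigma of junction lines (px).
#' @param noise List `gaussian_sd` (additive read-noise SD, counts),
#'   `poisson_gain` (variance per count of the mean-scaled component) and
#'   `blur_sigma` (optical blur in px). Zero all three for exact rasterized
#'   geometry.
#' @param intensity_levels Named list mapping channel
#'   (`nuclei`, `junctions`, `actin`, `transmitted`) to
#'   `c(background, foreground)` counts on the 16-bit scale.
#' @param jitter Grid-jitter fraction of the lattice spacing.
#' @param seed Integer seed; rendering is bit-identical for identical specs.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(field_size = c(512L, 512L), n_cells = 36L,
                       layout = c("jittered_grid", "uniform_random"),
                       nucleus_axes_range = c(8, 14), junction_width = 1.5,
                       noise = list(gaussian_sd = 150, poisson_gain = 0.05,
                                    blur_sigma = 1),
                       intensity_levels = list(
                         nuclei = c(background = 400, foreground = 14000),
                         junctions = c(background = 400, foreground = 12000),
                         actin = c(background = 500, foreground = 9000),
                         transmitted = c(background = 28000,
                                         foreground = 36000)),
                       jitter = 0.25, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(length(field_size) == 2, all(field_size >= 64),
            n_cells >= 1, nucleus_axes_range[1] <= nucleus_axes_range[2])
  structure(list(field_size = as.integer(field_size),
                 n_cells = as.integer(n_cells), layout = layout,
                 nucleus_axes_range = nucleus_axes_range,
                 junction_width = junction_width, noise = noise,
                 intensity_levels = intensity_levels, jitter = jitter,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a scene
#'
#' Places cell seed points, rasterizes their Voronoi tessellation, draws one
#' ellipse nucleus per cell, and exports the ground-truth object table
#' (analytic centroid and area `pi * a * b` per nucleus, pixel area per
#' cell region). Deterministic under the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @return A `scene`: `spec`, `seeds` (n x 2 matrix, row/col), `labels`
#'   (Voronoi region of every pixel), `boundary` (logical junction mask),
#'   `truth` (per-cell table), `n_rejected` (placements dropped for overlap).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  H <- spec$field_size[1]; W <- spec$field_size[2]
  n <- spec$n_cells
  min_space <- 2 * spec$nucleus_axes_range[2] + 2
  if (spec$layout == "jittered_grid") {
    gr <- ceiling(sqrt(n * H / W)); gc <- ceiling(n / gr)
    sp_r <- H / gr; sp_c <- W / gc
    if (min(sp_r, sp_c) < min_space)
      stop("placement error: ", n, " cells cannot fit the field at minimum spacing")
    centers <- expand.grid(r = (seq_len(gr) - 0.5) * sp_r,
                           c = (seq_len(gc) - 0.5) * sp_c)
    centers <- centers[sample.int(nrow(centers), n), ]
    seeds <- cbind(centers$r + stats::runif(n, -spec$jitter, spec$jitter) * sp_r,
                   centers$c + stats::runif(n, -spec$jitter, spec$jitter) * sp_c)
    n_rejected <- 0L
  } else {
    seeds <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(seeds) < n && tries < 200L * n) {
      tries <- tries + 1L
      p <- c(stats::runif(1, min_space / 2, H - min_space / 2),
             stats::runif(1, min_space / 2, W - min_space / 2))
      if (nrow(seeds) == 0 ||
          min(sqrt((seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2)) >= min_space)
        seeds <- rbind(seeds, p)
    }
    if (nrow(seeds) < n)
      stop("placement error: could not place ", n, " cells at minimum spacing")
    n_rejected <- tries - n
  }
  # rasterized Voronoi assignment
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  best <- matrix(Inf, H, W); labels <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    d2 <- (rows - seeds[i, 1])^2 + (cols - seeds[i, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]; labels[upd] <- i
  }
  boundary <- matrix(FALSE, H, W)
  boundary[-H, ] <- boundary[-H, ] | (labels[-H, ] != labels[-1, ])
  boundary[, -W] <- boundary[, -W] | (labels[, -W] != labels[, -1])
  a <- stats::runif(n, spec$nucleus_axes_range[1], spec$nucleus_axes_range[2])
  b <- stats::runif(n, spec$nucleus_axes_range[1], spec$nucleus_axes_range[2])
  theta <- stats::runif(n, 0, pi)
  cell_area <- tabulate(labels, n)
  truth <- data.frame(cell = seq_len(n),
                      centroid_row = seeds[, 1], centroid_col = seeds[, 2],
                      axis_a = a, axis_b = b, theta = theta,
                      nucleus_area = pi * a * b, cell_area_px = cell_area)
  structure(list(spec = spec, seeds = seeds, labels = labels,
                 boundary = boundary, truth = truth,
                 n_rejected = n_rejected),
            class = "scene")
}

# Distance of every pixel to the nearest TRUE pixel of a mask.
dist_to_mask <- function(mask) {
  inv <- matrix(1, nrow(mask), ncol(mask))
  inv[mask] <- 0
  EBImage::imageData(EBImage::distmap(EBImage::Image(inv)))
}

rasterize_nuclei <- function(scene) {
  H <- scene$spec$field_size[1]; W <- scene$spec$field_size[2]
  out <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(scene$truth))) {
    tr <- scene$truth[i, ]
    ext <- ceiling(max(tr$axis_a, tr$axis_b)) + 1L
    rr <- max(1L, floor(tr$centroid_row - ext)):min(H, ceiling(tr$centroid_row + ext))
    cc <- max(1L, floor(tr$centroid_col - ext)):min(W, ceiling(tr$centroid_col + ext))
    dr <- outer(rr - tr$centroid_row, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - tr$centroid_col)
    u <- dr * cos(tr$theta) + dc * sin(tr$theta)
    v <- -dr * sin(tr$theta) + dc * cos(tr$theta)
    out[rr, cc] <- out[rr, cc] | ((u / tr$axis_a)^2 + (v / tr$axis_b)^2 <= 1)
  }
  out
}

# Optical blur + additive and mean-scaled noise + 16-bit quantization.
finish_render <- function(img, noise) {
  if (noise$blur_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                             sigma = noise$blur_sigma))
  if (noise$gaussian_sd > 0)
    img <- img + stats::rnorm(length(img), 0, noise$gaussian_sd)
  if (noise$poisson_gain > 0)
    img <- img + stats::rnorm(length(img), 0,
                              sqrt(noise$poisson_gain * pmax(img, 0)))
  matrix(pmin(pmax(round(img), 0), 65535), nrow(img), ncol(img))
}

#' Render a fluorescence channel of a scene
#'
#' `nuclei`: filled ellipses. `junctions`: Voronoi edges with a Gaussian
#' cross-section of sigma `junction_width`. `actin`: cortical bands just
#' inside the cell boundaries plus sparse interior fibers. All channels then
#' receive optical blur, additive Gaussian and mean-scaled ("Poisson-like")
#' noise per the spec, and are quantized to 16-bit counts.
#'
#' @param scene A [generate_scene()] result.
#' @param channel `"nuclei"`, `"junctions"` or `"actin"`.
#' @return 16-bit intensity matrix.
#' @export
render_fluorescence <- function(scene,
                                channel = c("nuclei", "junctions", "actin")) {
  channel <- match.arg(channel)
  lev <- scene$spec$intensity_levels[[channel]]
  if (is.null(lev)) stop("no intensity levels configured for ", channel)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(scene$spec$seed + match(channel,
                                   c("nuclei", "junctions", "actin")) * 101L)
  H <- scene$spec$field_size[1]; W <- scene$spec$field_size[2]
  bg <- lev[[1]]; fg <- lev[[2]]
  img <- if (channel == "nuclei") {
    bg + (fg - bg) * rasterize_nuclei(scene)
  } else if (channel == "junctions") {
    d <- dist_to_mask(scene$boundary)
    bg + (fg - bg) * exp(-d^2 / (2 * scene$spec$junction_width^2))
  } else {
    d <- dist_to_mask(scene$boundary)
    cortex <- exp(-(d - 2)^2 / (2 * 1.5^2))
    fibers <- matrix(0, H, W)
    for (i in seq_len(nrow(scene$truth))) {
      for (q in 1:2) {
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 8, 20)
        p0 <- scene$seeds[i, ] + c(stats::runif(1, -4, 4), stats::runif(1, -4, 4))
        t <- seq(-len / 2, len / 2, by = 0.5)
        rr <- round(p0[1] + t * cos(ang)); cc <- round(p0[2] + t * sin(ang))
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        fibers[cbind(rr[ok], cc[ok])] <- 1
      }
    }
    bg + (fg - bg) * pmin(0.9 * cortex + 0.7 * fibers, 1)
  }
  finish_render(img, scene$spec$noise)
}

#' Render the transmitted-light channel of a scene
#'
#' A deterministic function of the scene with the qualitative features of
#' phase-contrast input: a bright halo with a dark relief along cell
#' boundaries, shading-gradient relief plus mild phase-darkening over nuclei,
#' and a low-frequency textured background, followed by the configured noise
#' model. Every fluorescence channel is a learnable function of this image
#' within a local receptive field (the nuclei and junction geometry is
#' encoded in the relief and halo).
#'
#' @param scene A [generate_scene()] result.
#' @return 16-bit intensity matrix.
#' @export
render_transmitted <- function(scene) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(scene$spec$seed + 977L)
  lev <- scene$spec$intensity_levels$transmitted
  bg <- lev[[1]]; fg <- lev[[2]]
  H <- scene$spec$field_size[1]; W <- scene$spec$field_size[2]
  amp <- fg - bg
  d <- dist_to_mask(scene$boundary)
  halo <- exp(-d^2 / 2) - 0.6 * exp(-(d - 2.5)^2 / (2 * 1.5^2))
  nuc <- rasterize_nuclei(scene) * 1
  nucb <- EBImage::imageData(EBImage::gblur(EBImage::Image(nuc), sigma = 1.5))
  relief <- rbind(nucb[-1, ] - nucb[-H, ], 0)
  texture <- EBImage::imageData(EBImage::gblur(
    EBImage::Image(matrix(stats::rnorm(H * W), H, W)), sigma = 6))
  texture <- texture / max(stats::sd(texture), 1e-12)
  img <- bg + amp * (0.8 * halo + 0.9 * relief - 0.35 * nucb) +
    0.06 * amp * texture
  finish_render(img, scene$spec$noise)
}

#' Build a paired synthetic dataset
#'
#' Generates `n_frames` scenes (per-frame seeds derived from the master
#' seed), renders transmitted input and one fluorescence target per frame,
#' tiles every frame identically across channels, splits the tiles into
#' train/validation/test partitions, and optionally writes the
#' TIFF-plus-manifest layout consumed by the data-preparation tools.
#'
#' @param spec A [scene_spec()] (its `seed` is overridden per frame).
#' @param n_frames Number of frames to generate.
#' @param seed Master seed for frame seeds and the split.
#' @param channel Fluorescence target channel.
#' @param tile_size Tile side (default 256).
#' @param test_frac,val_frac Split fractions (defaults 0.2 / 0.1).
#' @param dir Optional output directory; when given, writes
#'   `transmitted/` and `fluor_<channel>/` TIFFs, `manifest.csv`
#'   (tile index with origins and split) and `ground_truth.csv`.
#' @return An `frm_tiles` dataset with an extra `truth` element (the
#'   per-frame object tables, frame-stamped) and `scenes` (the scene list).
#' @export
make_dataset <- function(spec, n_frames = 8L, seed = 1L, channel = "nuclei",
                         tile_size = 256L, test_frac = 0.2, val_frac = 0.1,
                         dir = NULL) {
  frame_seeds <- (as.numeric(spec$seed %% 100000L) * 10007 +
                    seq_len(n_frames) * 7919 + as.numeric(seed) %% 100000L * 104729) %%
    2147483647
  xs <- list(); ys <- list(); meta <- list(); truths <- list(); scenes <- list()
  k <- 0L
  for (f in seq_len(n_frames)) {
    sp <- spec; sp$seed <- as.integer(frame_seeds[f])
    sc <- generate_scene(sp)
    scenes[[f]] <- sc
    tr <- render_transmitted(sc)
    fl <- render_fluorescence(sc, channel)
    pair <- image_pair(tr, stats::setNames(list(fl), channel), bit_depth = 16L,
                       um_per_px = 1, frame_index = f - 1L,
                       source_id = sprintf("synth_%03d", f - 1L))
    tiles <- tile_frame(pair, tile_size)
    tru <- sc$truth; tru$frame <- f - 1L; tru$source_id <- pair$source_id
    truths[[f]] <- tru
    for (tl in tiles) {
      k <- k + 1L
      xs[[k]] <- tl$pixels_in
      ys[[k]] <- tl$pixels_out[[channel]]
      meta[[k]] <- data.frame(tile_id = k, source_id = tl$source_id,
                              origin_row = tl$origin["row"],
                              origin_col = tl$origin["col"],
                              stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  x <- array(unlist(xs), c(tile_size, tile_size, k))
  y <- array(unlist(ys), c(tile_size, tile_size, k))
  split <- split_dataset(meta$tile_id, test_frac, val_frac,
                         seed = as.integer(seed %% 100000L + 13L))
  data <- tile_dataset(x, y, meta, split, channel = channel)
  data$truth <- do.call(rbind, truths)
  data$scenes <- scenes
  if (!is.null(dir)) write_dataset(data, dir, channel)
  data
}

# Persist a dataset as the TIFF + manifest directory convention.
write_dataset <- function(data, dir, channel) {
  dir.create(file.path(dir, "transmitted"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, paste0("fluor_", channel)), showWarnings = FALSE)
  for (i in seq_len(dim(data$x)[3])) {
    fn <- sprintf("tile_%05d.tif", i)
    tiff::writeTIFF(data$x[, , i] / 65535, file.path(dir, "transmitted", fn),
                    bits.per.sample = 16L)
    tiff::writeTIFF(data$y[, , i] / 65535,
                    file.path(dir, paste0("fluor_", channel), fn),
                    bits.per.sample = 16L)
  }
  utils::write.csv(data$meta, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(data$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
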