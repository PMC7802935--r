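#' Read a paired transmitted-light / fluorescence frame set
#'
#' Reads a grayscale single- or multi-page TIFF of transmitted-light images
#' together with matched fluorescence TIFF(s), one page per frame, and returns
#' one image pair per page. Channels must be pre-aligned and share dimensions.
#'
#' @param transmitted_path Path to the transmitted-light TIFF.
#' @param fluorescence_paths Named character vector or list mapping channel
#'   name to a TIFF path with the same page count and dimensions.
#' @param um_per_px Physical pixel size in micrometers per pixel.
#' @param bit_depth Bit depth of the data (8, 14 or 16). Default `NULL`
#'   infers 8 or 16 from the file's bits-per-sample; 14-bit data (stored in
#'   16-bit containers) must be declared explicitly.
#' @return A list of `image_pair` objects, one per page, each holding
#'   `transmitted` (matrix of counts), `fluorescence` (named list of
#'   matrices), `bit_depth`, `um_per_px`, `frame_index` (0-based) and
#'   `source_id`.
#' @export
read_image_pair <- function(transmitted_path, fluorescence_paths, um_per_px,
                            bit_depth = NULL) {
  stopifnot(um_per_px > 0)
  tr <- read_tiff_stack(transmitted_path)
  fl <- lapply(fluorescence_paths, read_tiff_stack)
  if (is.null(names(fl)) || any(names(fl) == ""))
    names(fl) <- paste0("channel", seq_along(fl))
  n <- length(tr$pages)
  for (ch in names(fl)) {
    if (length(fl[[ch]]$pages) != n)
      stop("page count mismatch: transmitted has ", n, ", ", ch, " has ",
           length(fl[[ch]]$pages))
    for (p in seq_len(n))
      if (!identical(dim(fl[[ch]]$pages[[p]]), dim(tr$pages[[p]])))
        stop("alignment error: channel '", ch, "' page ", p,
             " dimensions differ from transmitted")
  }
  bd <- if (is.null(bit_depth)) tr$bits else as.integer(bit_depth)
  if (!bd %in% c(8L, 14L, 16L)) stop("unsupported bit depth: ", bd)
  sid <- tools::file_path_sans_ext(basename(transmitted_path))
  lapply(seq_len(n), function(p) {
    image_pair(transmitted = tr$pages[[p]],
               fluorescence = lapply(fl, function(s) s$pages[[p]]),
               bit_depth = bd, um_per_px = um_per_px,
               frame_index = if (n > 1) p - 1L else NA_integer_,
               source_id = if (n > 1) paste0(sid, "_f", p - 1L) else sid)
  })
}

# Read all pages of a grayscale TIFF as integer-count matrices.
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages)
    if (length(dim(p)) == 3)
      stop("unsupported format: multi-sample (color) TIFF: ", path)
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(pages[[1]]) > 255) 16L else 8L
  list(pages = lapply(pages, function(p) {
    storage.mode(p) <- "double"
    matrix(p, nrow(p), ncol(p))   # drop TIFF info attributes
  }), bits = as.integer(bits))
}

#' @rdname read_image_pair
#' @param transmitted,fluorescence,frame_index,source_id Fields of the pair;
#'   see the return value description.
#' @export
image_pair <- function(transmitted, fluorescence, bit_depth, um_per_px,
                       frame_index = NA_integer_, source_id = "frame") {
  stopifnot(is.matrix(transmitted), is.list(fluorescence))
  for (ch in names(fluorescence))
    if (!identical(dim(fluorescence[[ch]]), dim(transmitted)))
      stop("alignment error: channel '", ch, "' dimensions differ")
  maxv <- 2^bit_depth - 1
  allv <- c(range(transmitted),
            unlist(lapply(fluorescence, range), use.names = FALSE))
  if (min(allv) < 0 || max(allv) > maxv)
    stop("intensities outside [0, 2^bit_depth - 1]")
  if (um_per_px <= 0) stop("um_per_px must be positive")
  structure(list(transmitted = transmitted, fluorescence = fluorescence,
                 bit_depth = as.integer(bit_depth), um_per_px = um_per_px,
                 frame_index = frame_index, source_id = source_id),
            class = "image_pair")
}

#' Convert between bit depths
#'
#' Linear full-range map `v -> round(v * (2^dst - 1) / (2^src - 1))`:
#' monotone, with 0 mapping to 0 and the source maximum to the destination
#' maximum. This is how natively 14-bit camera data are brought onto the
#' 16-bit histogram before intensity analysis.
#'
#' @param image Matrix (or array) of integer counts.
#' @param src_bits,dst_bits Source and destination bit depths (8, 14 or 16).
#' @param stretch If `TRUE`, use a per-image min-max stretch onto the
#'   destination range instead of the full-range map.
#' @return The converted image.
#' @export
normalize_bit_depth <- function(image, src_bits, dst_bits, stretch = FALSE) {
  stopifnot(src_bits %in% c(8, 14, 16), dst_bits %in% c(8, 14, 16))
  smax <- 2^src_bits - 1; dmax <- 2^dst_bits - 1
  if (max(image) > smax || min(image) < 0)
    stop("pixel values outside the source bit-depth range")
  if (stretch) {
    lo <- min(image); hi <- max(image)
    if (hi == lo) return(image * 0)
    return(round((image - lo) * (dmax / (hi - lo))))
  }
  round(image * (dmax / smax))
}

#' Tile a frame into non-overlapping sub-images
#'
#' Slices the transmitted and all fluorescence channels identically into a
#' grid of `tile_size` x `tile_size` sub-images. When a frame dimension is not
#' a multiple of `tile_size`, the grid is centered and the remainder cropped
#' symmetrically (with a warning).
#'
#' @param pair An `image_pair`.
#' @param tile_size Side length of the square tiles (default 256).
#' @return A list of tiles; each tile has `pixels_in` (matrix),
#'   `pixels_out` (named list of matrices), `origin` (0-based `(row, col)` in
#'   the source frame) and `source_id`.
#' @export
tile_frame <- function(pair, tile_size = 256L) {
  stopifnot(inherits(pair, "image_pair"))
  H <- nrow(pair$transmitted); W <- ncol(pair$transmitted)
  if (H < tile_size || W < tile_size)
    stop("frame (", H, "x", W, ") smaller than tile size ", tile_size)
  nr <- H %/% tile_size; nc <- W %/% tile_size
  r0 <- (H - nr * tile_size) %/% 2L
  c0 <- (W - nc * tile_size) %/% 2L
  if (r0 > 0 || c0 > 0)
    warning("frame not a multiple of tile size; cropping ", H - nr * tile_size,
            " row(s) and ", W - nc * tile_size, " column(s) symmetrically")
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr) - 1L) for (j in seq_len(nc) - 1L) {
    rr <- r0 + i * tile_size + seq_len(tile_size)
    cc <- c0 + j * tile_size + seq_len(tile_size)
    k <- k + 1L
    tiles[[k]] <- list(
      pixels_in = pair$transmitted[rr, cc, drop = FALSE],
      pixels_out = lapply(pair$fluorescence, function(m)
        m[rr, cc, drop = FALSE]),
      origin = c(row = r0 + i * tile_size, col = c0 + j * tile_size),
      source_id = pair$source_id)
  }
  tiles
}

#' Pooled normalization statistics
#'
#' Mean and population standard deviation pooled over all pixels of all
#' supplied tiles of one channel. These statistics drive the z-normalization
#' applied before training and the de-normalization applied to predictions.
#'
#' @param tiles 3-d array `(H, W, N)` of tiles, or a list of matrices.
#' @return A `norm_stats` object with fields `mean`, `std` and `degenerate`
#'   (`TRUE` when the pooled variance is zero, in which case normalization
#'   refuses to divide).
#' @export
compute_norm_stats <- function(tiles) {
  v <- if (is.list(tiles)) unlist(tiles, use.names = FALSE) else as.numeric(tiles)
  if (length(v) == 0) stop("no tiles supplied")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))   # population SD, fixed for reproducibility
  structure(list(mean = m, std = s, degenerate = s == 0),
            class = "norm_stats")
}

#' @rdname compute_norm_stats
#' @param mean,std Statistics in counts.
#' @export
norm_stats <- function(mean, std) {
  if (std < 0) stop("std must be nonnegative")
  structure(list(mean = mean, std = std, degenerate = std == 0),
            class = "norm_stats")
}

#' Z-normalize / de-normalize with fixed channel statistics
#'
#' `normalize_tiles` maps `v -> (v - mean) / std`; `denormalize` is its exact
#' inverse (`v -> v * std + mean`). Predictions are de-normalized with the
#' fluorescence channel's statistics before being written out.
#'
#' @param tiles Numeric array (any shape).
#' @param stats A `norm_stats` object with `std > 0`.
#' @return Array of the same shape.
#' @export
normalize_tiles <- function(tiles, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$std == 0) stop("degenerate statistics: std is 0")
  (tiles - stats$mean) / stats$std
}

#' @rdname normalize_tiles
#' @export
denormalize <- function(tiles, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$std == 0) stop("degenerate statistics: std is 0")
  tiles * stats$std + stats$mean
}

#' Reproducible train/validation/test split
#'
#' Holds out a random `test_frac` of tiles as the test set, then `val_frac`
#' of the remaining (training) tiles for validation; counts use floor
#' rounding. Identical inputs and seed always reproduce the identical split.
#'
#' @param tile_ids Character or integer vector of tile identifiers.
#' @param test_frac Fraction held out for testing (default 0.2).
#' @param val_frac Fraction of the remaining training tiles held out for
#'   validation (default 0.1).
#' @param seed Integer seed.
#' @param group Optional vector (same length as `tile_ids`) of source-frame
#'   ids; when given, all tiles of a frame land in the same partition
#'   (leakage control; off by default).
#' @return A `dataset_split` with disjoint `test_ids`, `validation_ids`,
#'   `train_ids` whose union is `tile_ids`.
#' @export
split_dataset <- function(tile_ids, test_frac = 0.2, val_frac = 0.1,
                          seed = 1L, group = NULL) {
  if (length(tile_ids) == 0) stop("empty tile id list")
  if (test_frac < 0 || test_frac >= 1 || val_frac < 0 || val_frac >= 1)
    stop("fractions must lie in [0, 1)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (is.null(group)) {
    n <- length(tile_ids)
    perm <- sample.int(n)
    n_test <- floor(test_frac * n)
    n_val <- floor(val_frac * (n - n_test))
    test <- tile_ids[perm[seq_len(n_test)]]
    val <- tile_ids[perm[n_test + seq_len(n_val)]]
    train <- tile_ids[perm[setdiff(seq_len(n), seq_len(n_test + n_val))]]
  } else {
    stopifnot(length(group) == length(tile_ids))
    gs <- unique(group)
    perm <- sample(gs)
    ng_test <- floor(test_frac * length(gs))
    ng_val <- floor(val_frac * (length(gs) - ng_test))
    gtest <- perm[seq_len(ng_test)]
    gval <- perm[ng_test + seq_len(ng_val)]
    test <- tile_ids[group %in% gtest]
    val <- tile_ids[group %in% gval]
    train <- setdiff(tile_ids, c(test, val))
  }
  structure(list(test_ids = test, validation_ids = val, train_ids = train,
                 test_frac = test_frac, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Assemble a tile dataset for model fitting
#'
#' Packs matched input/target tiles and their split assignment into the
#' container consumed by [frm_fit()].
#'
#' @param x 3-d array `(H, W, N)` of transmitted-light tiles (counts).
#' @param y 3-d array `(H, W, N)` of fluorescence target tiles (counts).
#' @param meta Optional data frame with one row per tile; a `split` column
#'   (`"train"`, `"validation"`, `"test"`) is required unless `split` is given.
#' @param split Optional `dataset_split` over `meta$tile_id` (or tile index).
#' @param channel Name of the target fluorescence channel.
#' @return An object of class `frm_tiles`.
#' @export
tile_dataset <- function(x, y, meta = NULL, split = NULL, channel = "fluor") {
  stopifnot(length(dim(x)) == 3, identical(dim(x), dim(y)))
  n <- dim(x)[3]
  if (is.null(meta))
    meta <- data.frame(tile_id = seq_len(n), source_id = NA_character_,
                       origin_row = 0L, origin_col = 0L,
                       stringsAsFactors = FALSE)
  if (!is.null(split)) {
    meta$split <- "train"
    meta$split[meta$tile_id %in% split$test_ids] <- "test"
    meta$split[meta$tile_id %in% split$validation_ids] <- "validation"
  }
  if (is.null(meta$split)) stop("no split assignment provided")
  structure(list(x = x, y = y, meta = meta, channel = channel),
            class = "frm_tiles")
}

#' @export
print.frm_tiles <- function(x, ...) {
  d <- dim(x$x)
  cat("Tile dataset: ", d[3], " tiles of ", d[1], "x", d[2],
      " (channel: ", x$channel, ")\n", sep = "")
  print(table(x$meta$split))
  invisible(x)
}

# Subset of tiles in a given partition, as (H,W,N) arrays.
tiles_in_split <- function(data, which) {
  idx <- which(data$meta$split == which)
  list(x = data$x[, , idx, drop = FALSE],
       y = data$y[, , idx, drop = FALSE], idx = idx)
}
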