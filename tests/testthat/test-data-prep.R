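test_that("bit-depth conversion is the full-range linear map", {
  expect_equal(normalize_bit_depth(matrix(16383), 14, 16), matrix(65535))
  expect_equal(normalize_bit_depth(matrix(0), 14, 16), matrix(0))
  # mid-range value against high-precision evaluation of the map
  expect_equal(normalize_bit_depth(matrix(8191), 14, 16),
               matrix(round(8191 * 65535 / 16383)))
  expect_error(normalize_bit_depth(matrix(300), 8, 16), "outside")
})

test_that("bit-depth conversion is monotone and endpoint-exact for all pairs", {
  for (src in c(8, 14, 16)) for (dst in c(8, 14, 16)) {
    v <- sort(sample.int(2^src, 50) - 1L)
    out <- normalize_bit_depth(matrix(v), src, dst)
    expect_true(all(diff(out) >= 0), info = paste(src, "->", dst))
    expect_equal(normalize_bit_depth(matrix(2^src - 1), src, dst)[1],
                 2^dst - 1)
    expect_equal(normalize_bit_depth(matrix(0), src, dst)[1], 0)
  }
})

test_that("tiling produces the expected grid and reassembles bit-exactly", {
  set.seed(1)
  big <- matrix(as.numeric(sample.int(65536, 1024^2, replace = TRUE) - 1L),
                1024, 1024)
  pair <- image_pair(big, list(nuc = big), bit_depth = 16, um_per_px = 0.65)
  tiles <- tile_frame(pair, 256L)
  expect_length(tiles, 16L)     # a full camera frame chops into 16 sub-images
  rec <- matrix(0, 1024, 1024)
  for (tl in tiles)
    rec[tl$origin["row"] + 1:256, tl$origin["col"] + 1:256] <- tl$pixels_in
  expect_identical(rec, big)

  one <- tile_frame(image_pair(big[1:256, 1:256], list(n = big[1:256, 1:256]),
                               16, 1), 256L)
  expect_length(one, 1L)
  expect_identical(one[[1]]$pixels_in, big[1:256, 1:256])
})

test_that("non-multiple frames are center-cropped with hand-enumerated origins", {
  m <- matrix(runif(600 * 600, 0, 255), 600, 600)
  pair <- image_pair(round(m), list(f = round(m)), 8, 1)
  expect_warning(tiles <- tile_frame(pair, 256L), "cropping")
  expect_length(tiles, 4L)
  origins <- t(vapply(tiles, function(t) t$origin, c(row = 0, col = 0)))
  expect_setequal(origins[, "row"], c(44L, 300L))
  expect_setequal(origins[, "col"], c(44L, 300L))
  expect_error(tile_frame(image_pair(m[1:100, 1:100], list(f = m[1:100, 1:100]),
                                     8, 1), 256L), "smaller")
})

test_that("image pairs enforce channel alignment and intensity range", {
  a <- matrix(0, 64, 64); b <- matrix(0, 32, 32)
  expect_error(image_pair(a, list(f = b), 16, 1), "alignment")
  expect_error(image_pair(a - 1, list(f = a), 16, 1), "intensities")
  expect_error(image_pair(a, list(f = a), 16, -1), "positive")
})

test_that("norm stats pool all pixels and flag zero variance", {
  t0 <- matrix(0, 8, 8); t1 <- matrix(1, 8, 8)
  s <- compute_norm_stats(list(t0, t1))
  expect_equal(s$mean, 0.5)
  sc <- compute_norm_stats(list(t1, t1))
  expect_equal(sc$mean, 1)
  expect_equal(sc$std, 0)
  expect_true(sc$degenerate)
  expect_error(normalize_tiles(t1, sc), "degenerate")
})

test_that("normalization is a z-score and denormalize inverts it", {
  set.seed(2)
  tiles <- array(runif(16 * 16 * 10, 0, 65535), c(16, 16, 10))
  s <- compute_norm_stats(tiles)
  z <- normalize_tiles(tiles, s)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  back <- denormalize(z, s)
  expect_lt(max(abs(back - tiles) / pmax(abs(tiles), 1)), 1e-6)
  expect_equal(normalize_tiles(matrix(200), norm_stats(100, 50))[1], 2)
  expect_equal(normalize_tiles(matrix(s$mean, 4, 4), s), matrix(0, 4, 4))
})

test_that("dataset split honors the 20/10 floor rule and determinism", {
  sp <- split_dataset(1:100, seed = 3)
  expect_length(sp$test_ids, 20)
  expect_length(sp$validation_ids, 8)
  expect_length(sp$train_ids, 72)
  sp2 <- split_dataset(1:100, seed = 3)
  expect_identical(sp, sp2)
  all_train <- split_dataset(1:100, test_frac = 0, val_frac = 0, seed = 1)
  expect_length(all_train$train_ids, 100)
  expect_error(split_dataset(integer(), seed = 1), "empty")
})

test_that("splits are disjoint and exhaustive across random settings", {
  set.seed(7)
  for (q in 1:20) {
    n <- sample(5:500, 1)
    tf <- runif(1, 0, 0.5); vf <- runif(1, 0, 0.5)
    sp <- split_dataset(seq_len(n), tf, vf, seed = sample.int(1e6, 1))
    ids <- c(sp$test_ids, sp$validation_ids, sp$train_ids)
    expect_equal(sort(ids), seq_len(n))
    expect_equal(anyDuplicated(ids), 0)
    expect_length(sp$test_ids, floor(tf * n))
    expect_length(sp$validation_ids, floor(vf * (n - floor(tf * n))))
  }
})

test_that("grouped split keeps all tiles of a frame together", {
  group <- rep(1:10, each = 8)
  sp <- split_dataset(seq_len(80), seed = 4, group = group)
  for (part in list(sp$test_ids, sp$validation_ids, sp$train_ids)) {
    gs <- unique(group[part])
    expect_true(all(table(group[part]) == 8) || length(part) == 0)
    expect_equal(sort(part), sort(which(group %in% gs)))
  }
})

test_that("TIFF pairs round-trip through the directory convention", {
  dir <- withr::local_tempdir()
  d <- make_dataset(noiseless_spec(seed = 3), n_frames = 2, seed = 1,
                    tile_size = 64, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  p <- read_image_pair(file.path(dir, "transmitted", "tile_00001.tif"),
                       c(nuclei = file.path(dir, "fluor_nuclei",
                                            "tile_00001.tif")),
                       um_per_px = 1)
  expect_length(p, 1)
  expect_equal(p[[1]]$bit_depth, 16L)
  expect_identical(p[[1]]$transmitted, d$x[, , 1])
  expect_identical(p[[1]]$fluorescence$nuclei, d$y[, , 1])
})

test_that("multi-page stacks yield one pair per page with frame indices", {
  dir <- withr::local_tempdir()
  set.seed(5)
  pages <- lapply(1:4, function(i) matrix(runif(32 * 32), 32, 32))
  tiff::writeTIFF(pages, file.path(dir, "tr.tif"), bits.per.sample = 16)
  tiff::writeTIFF(pages, file.path(dir, "fl.tif"), bits.per.sample = 16)
  ps <- read_image_pair(file.path(dir, "tr.tif"),
                        c(nuc = file.path(dir, "fl.tif")), um_per_px = 1)
  expect_length(ps, 4)
  expect_equal(vapply(ps, `[[`, 0L, "frame_index"), 0:3)
  # mismatched dimensions across channels
  tiff::writeTIFF(matrix(0, 16, 16), file.path(dir, "bad.tif"))
  expect_error(read_image_pair(file.path(dir, "tr.tif"),
                               c(n = file.path(dir, "bad.tif")), 1),
               "page count|alignment")
})
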