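test_that("stitch configuration enforces its bounds", {
  expect_error(stitch_config(stride = 0), "stride")
  expect_error(stitch_config(stride = 300, window = 256), "stride")
  expect_error(stitch_config(border_exclude = 128, window = 256), "border")
  # margins so wide that strided interiors would leave gaps are rejected
  expect_error(stitch_config(256, stride = 256, border_exclude = 16),
               "coverage")
})

test_that("window origins follow the stride with a flush final origin", {
  cfg <- stitch_config(256, 64, 16)
  expect_equal(nrow(window_origins(256, 256, cfg)), 1)
  expect_equal(unlist(window_origins(256, 256, cfg)[1, ],
                      use.names = FALSE), c(0, 0))
  wo <- window_origins(1024, 1024, cfg)
  expect_equal(nrow(wo), 169)                      # (1024-256)/64+1 = 13 per axis
  expect_setequal(unique(wo$row), seq(0, 768, by = 64))
  wo2 <- window_origins(300, 300, cfg)
  expect_setequal(unique(wo2$row), c(0, 44))       # flush final origin
  expect_setequal(unique(wo2$col), c(0, 44))
  expect_error(window_origins(100, 300, cfg), "smaller")
})

test_that("a constant oracle stitches to a constant image", {
  img <- matrix(runif(300 * 280, 0, 65535), 300, 280)
  out <- sliding_window_predict(function(p) p * 0 + 1234, img,
                                stitch_config(256, 64, 16))
  expect_equal(dim(out), dim(img))
  expect_true(all(out == 1234))
})

test_that("stitching equals a pixel-wise oracle for any contract-valid config", {
  set.seed(11)
  f <- function(p) 0.4 * p + 250
  for (q in 1:6) {
    H <- sample(256:420, 1); W <- sample(256:420, 1)
    w <- 128L
    b <- sample.int(w %/% 2, 1) - 1L
    stride <- sample.int(w - 2L * b, 1)
    img <- matrix(runif(H * W, 0, 65535), H, W)
    out <- sliding_window_predict(f, img, stitch_config(w, stride, b),
                                  clamp = FALSE)
    expect_lt(max(abs(out - f(img))), 1e-5)
    expect_false(any(is.na(out)))
  }
})

test_that("stride = window with no border equals non-overlapping tiling", {
  img <- matrix(runif(512 * 512, 0, 65535), 512, 512)
  f <- function(p) sqrt(p)
  out <- sliding_window_predict(f, img, stitch_config(256, 256, 0),
                                clamp = FALSE)
  expect_equal(out, f(img), tolerance = 1e-12)
})

test_that("coverage is at least 1 everywhere and symmetric for square images", {
  img <- matrix(0, 300, 300)
  r <- sliding_window_predict(function(p) p, img, stitch_config(256, 64, 16),
                              return_coverage = TRUE)
  expect_gte(min(r$coverage), 1)
  expect_equal(r$coverage, t(r$coverage))
  expect_equal(r$coverage, r$coverage[300:1, 300:1])  # 180-degree symmetry
})

test_that("images smaller than the window are reflect-padded and cropped back", {
  img <- matrix(runif(100 * 80, 0, 1000), 100, 80)
  f <- function(p) 2 * p
  out <- sliding_window_predict(f, img, stitch_config(256, 64, 16),
                                clamp = FALSE)
  expect_equal(dim(out), dim(img))
  expect_lt(max(abs(out - f(img))), 1e-9)
})

test_that("timelapse prediction is frame-independent and order-preserving", {
  set.seed(12)
  stack <- lapply(1:5, function(i) matrix(runif(280 * 280, 0, 100), 280, 280))
  f <- function(p) p + 7
  cfg <- stitch_config(256, 128, 8)
  out <- predict_timelapse(f, stack, cfg, clamp = FALSE)
  expect_length(out, 5)
  for (i in c(1, 3, 5))
    expect_equal(out[[i]], sliding_window_predict(f, stack[[i]], cfg,
                                                  clamp = FALSE))
  expect_error(predict_timelapse(f, list(stack[[1]], matrix(0, 10, 10)), cfg),
               "mixed")
})

test_that("a trained model stitches a full frame to plausible fluorescence", {
  fit <- tiny_model()
  sc <- generate_scene(noiseless_spec(seed = 77))
  img <- render_transmitted(sc)
  truth <- render_fluorescence(sc, "nuclei")
  pred <- predict(fit, img, type = "image",
                  stitch = stitch_config(64, 32, 4))
  expect_equal(dim(pred), dim(img))
  expect_true(all(pred >= 0 & pred <= 65535))
  expect_gt(pcc(truth, pred), 0.3)   # modest fit after 5 epochs
})

test_that("pixel-size correction scales dimensions and round-trips", {
  set.seed(13)
  img <- matrix(runif(120 * 90), 120, 90)
  out <- rescale_to_reference(img, src_um_per_px = 7.3, ref_um_per_px = 6.5,
                              src_magnification = 4, ref_magnification = 5)
  factor <- (7.3 / 4) / (6.5 / 5)
  expect_equal(attr(out, "factor"), factor)
  expect_equal(dim(out), round(dim(img) * factor))
  back <- rescale_to_native(out, dim(img))
  expect_equal(dim(back), dim(img))
  expect_lt(mean(abs(back - img)), 0.2)    # interpolation tolerance
  ident <- rescale_to_reference(img, 6.5, 6.5)
  expect_equal(dim(ident), dim(img))
  expect_equal(as.numeric(ident), as.numeric(img))
  expect_error(rescale_to_reference(img, -1, 5), "positive")
})
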