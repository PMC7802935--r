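test_that("pcc matches the closed formula and the reference implementation", {
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(pcc(c(1, 2, 3, 4), 10 - c(1, 2, 3, 4)), -1)
  # brute-force formula evaluation for R=[1,2,3,4], G=[1,2,3,5]
  expect_equal(pcc(c(1, 2, 3, 4), c(1, 2, 3, 5)), 6.5 / sqrt(5 * 8.75))
  set.seed(1)
  for (q in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(pcc(a, b), stats::cor(a, b))   # independent reference
    expect_equal(pcc(a, b), pcc(b, a))
    expect_equal(pcc(2.3 * a + 7, b), pcc(a, b))
  }
  expect_error(pcc(rep(1, 5), rnorm(5)), "constant")
})

test_that("scaled-MAD outlier removal matches hand arithmetic", {
  # median 1, MAD 0 -> only values != median are removed
  expect_equal(as.numeric(remove_outliers(c(1, 1, 1, 1, 100))), rep(1, 4))
  v <- c(9.8, 10, 10.1, 10.3, 25)
  # median 10.1, scaled MAD = 1.4826 * 0.3; |25 - 10.1| > 3 * 0.44478
  expect_equal(as.numeric(remove_outliers(v)), v[1:4])
  expect_equal(as.numeric(remove_outliers(rep(3, 6))), rep(3, 6))
  expect_equal(as.numeric(remove_outliers(v, rule = "none")), v)
  expect_error(remove_outliers(numeric()), "empty")
})

test_that("feature filtering partitions by suprathreshold pixel count", {
  cfg <- metric_config(feature_threshold = 5000, min_feature_pixels = 10)
  imgs <- list(matrix(0, 32, 32),                        # background
               disc_image(32, 32, c(16, 16), 6),         # feature-positive
               disc_image(32, 32, c(16, 16), 1.5))       # too few pixels
  f <- filter_feature_positive(imgs, cfg)
  expect_equal(f$positive, c(FALSE, TRUE, FALSE))
  expect_equal(f$positive_idx, 2L)
})

test_that("generated scenes are filtered by their known object content", {
  tiles <- list()
  for (i in 1:10) {
    if (i <= 4) {
      sc <- generate_scene(noiseless_spec(field = c(64L, 64L), n_cells = 1L,
                                          seed = i))
      tiles[[i]] <- render_fluorescence(sc, "nuclei")
    } else tiles[[i]] <- matrix(400, 64, 64)
  }
  f <- filter_feature_positive(tiles, metric_config(feature_threshold = 5000))
  expect_equal(f$positive_idx, 1:4)
})

test_that("accuracy score P is exact for perfect predictions and excludes background", {
  cfg <- metric_config(feature_threshold = 5000)
  pos <- lapply(1:5, function(i) disc_image(32, 32, c(16, 16), 4 + i))
  bg <- lapply(1:3, function(i) matrix(stats::rnorm(1024, 200, 30), 32, 32))
  r1 <- accuracy_score_P(pos, pos, cfg)
  expect_equal(r1$P$mean, 1)
  expect_equal(r1$P$n, 5)
  # adding background-only tiles does not change P (they are filtered out)
  set.seed(4)
  noisy <- lapply(pos, function(m) m + matrix(rnorm(1024, 0, 500), 32, 32))
  pa <- accuracy_score_P(pos, noisy, cfg)
  pb <- accuracy_score_P(c(pos, bg), c(noisy, bg), cfg)
  expect_equal(pa$P$mean, pb$P$mean)
  expect_error(accuracy_score_P(bg, bg, cfg), "feature-positive")
})

test_that("P decreases monotonically with prediction noise", {
  set.seed(5)
  truth <- lapply(1:6, function(i) disc_image(64, 64, c(32, 32), 10 + i))
  cfg <- metric_config(feature_threshold = 5000)
  means <- vapply(c(100, 1000, 5000, 20000), function(amp) {
    pred <- lapply(truth, function(m) m + matrix(rnorm(4096, 0, amp), 64, 64))
    accuracy_score_P(truth, pred, cfg)$P$mean
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("segmentation pcc restricts to the ground-truth mask", {
  cfg <- metric_config(feature_threshold = 100)
  t4 <- matrix(c(500, 500, 500, 0,
                 500, 500, 0, 0,
                 0, 0, 0, 0,
                 0, 0, 0, 50), 4, 4)
  t4[1, 1] <- 700; t4[2, 2] <- 300
  p4 <- matrix(rev(seq_len(16) * 40), 4, 4)
  mask <- t4 > 100
  expected <- stats::cor(t4[mask], p4[mask])  # independent masked evaluation
  sp <- segmentation_pcc(list(t4), list(p4), cfg)
  expect_equal(sp$per_image$pcc[1], expected)
  expect_equal(sp$per_image$mask_pixels[1], sum(mask))
  # perfect prediction scores 1; threshold above max skips everything
  imgs <- lapply(1:3, function(i) disc_image(32, 32, c(16, 16), 8, fg = 5000 + i * 100))
  expect_equal(segmentation_pcc(imgs, imgs,
                                metric_config(feature_threshold = 100))$summary$mean, 1)
  sk <- segmentation_pcc(imgs, imgs, metric_config(feature_threshold = 65535))
  expect_equal(sk$summary$n, 0)
  expect_equal(sk$n_skipped, 3)
})

test_that("cytofluorogram conserves counts and matches 1-d marginals", {
  set.seed(6)
  truth <- lapply(1:4, function(i) matrix(runif(1024, 0, 65535), 32, 32))
  pred <- lapply(1:4, function(i) matrix(runif(1024, 0, 65535), 32, 32))
  cfg <- metric_config(bins = 16)
  cy <- cytofluorogram(truth, pred, cfg, zoom_tau = 30000)
  expect_equal(sum(cy$counts), 4 * 1024)
  expect_equal(cy$n_pixels, 4 * 1024)
  tv <- unlist(lapply(truth, as.numeric))
  h <- hist(tv, breaks = cy$breaks, plot = FALSE)$counts
  expect_equal(rowSums(cy$counts), h)
  pv <- unlist(lapply(pred, as.numeric))
  hp <- hist(pv, breaks = cy$breaks, plot = FALSE)$counts
  expect_equal(colSums(cy$counts), hp)
  expect_equal(sum(cy$zoom$counts), sum(tv > 30000))
  # identical images put all mass on the diagonal
  cyd <- cytofluorogram(truth, truth, cfg)
  expect_equal(sum(diag(cyd$counts)), sum(cyd$counts))
})

test_that("automatic threshold separates foreground from background", {
  imgs <- lapply(1:4, function(i) disc_image(64, 64, c(32, 32), 12,
                                             fg = 20000, bg = 500))
  f <- filter_feature_positive(imgs, metric_config())
  expect_true(all(f$positive))
  expect_gt(f$tau, 500); expect_lt(f$tau, 20000)
})
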