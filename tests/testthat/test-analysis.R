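test_that("a single blob segments to one object at the right place", {
  img <- disc_image(128, 128, c(60, 70), 12)
  lm <- segment_nuclei(img, seg_config(blur_sigma = 2), um_per_px = 0.5)
  expect_equal(nrow(lm$objects), 1)
  expect_lt(abs(lm$objects$centroid_row - 60), 1)
  expect_lt(abs(lm$objects$centroid_col - 70), 1)
  expect_equal(lm$um_per_px, 0.5)
})

test_that("well-separated blobs are counted individually", {
  img <- pmax(disc_image(128, 128, c(30, 30), 10),
              disc_image(128, 128, c(90, 95), 10))
  lm <- segment_nuclei(img, seg_config(blur_sigma = 2))
  expect_equal(nrow(lm$objects), 2)
})

test_that("watershed splits touching blobs; without it they merge", {
  img <- pmax(disc_image(96, 96, c(48, 38), 11),
              disc_image(96, 96, c(48, 56), 11))
  with_ws <- segment_nuclei(img, seg_config(blur_sigma = 1, watershed = TRUE))
  without <- segment_nuclei(img, seg_config(blur_sigma = 1, watershed = FALSE))
  expect_equal(nrow(with_ws$objects), 2)
  expect_equal(nrow(without$objects), 1)
})

test_that("size exclusion drops objects outside the area bounds", {
  img <- pmax(disc_image(128, 128, c(30, 30), 3),
              disc_image(128, 128, c(90, 90), 12))
  lm <- segment_nuclei(img, seg_config(blur_sigma = 0.5, min_area = 100))
  expect_equal(nrow(lm$objects), 1)
  expect_gt(lm$objects$area[1], 300)
  expect_error(seg_config(min_area = 10, max_area = 5), "min_area")
})

test_that("count error is the absolute percent disagreement", {
  mk <- function(n) {
    labs <- matrix(0L, 40, 40 * n)
    for (i in seq_len(n)) labs[10:20, (i - 1) * 40 + 10:20] <- i
    label_map(labs)
  }
  expect_equal(count_error(mk(4), mk(4)), 0)
  expect_equal(count_error(mk(5), mk(4)), 20)
  expect_equal(count_error(mk(4), mk(5)), 25)
  expect_error(count_error(label_map(matrix(0L, 4, 4)), mk(1)), "undefined")
})

test_that("centroid displacements recover a known shift and flag unmatched", {
  labs <- matrix(0L, 64, 64)
  centers <- list(c(12, 12), c(40, 20), c(20, 48))
  for (i in seq_along(centers))
    labs[centers[[i]][1] + (-2:2), centers[[i]][2] + (-2:2)] <- i
  gt <- label_map(labs, um_per_px = 1)
  shifted <- matrix(0L, 64, 64)
  for (i in seq_along(centers))
    shifted[centers[[i]][1] + 3 + (-2:2), centers[[i]][2] + 4 + (-2:2)] <- i
  pred <- label_map(shifted, um_per_px = 1)
  d <- centroid_displacements(gt, pred, max_link_dist = 15)
  expect_equal(d$displacements_um, rep(5, 3))     # 3-4-5 triangle
  expect_equal(d$unmatched_gt + d$unmatched_pred, 0)
  expect_equal(centroid_displacements(gt, gt)$displacements_um, rep(0, 3))
  # an extra object beyond the cap is reported unmatched
  extra <- shifted; extra[58:62, 58:62] <- 4L
  d2 <- centroid_displacements(gt, label_map(extra), max_link_dist = 15)
  expect_equal(length(d2$displacements_um), 3)
  expect_equal(d2$unmatched_pred, 1)
  # symmetry: same multiset of distances either way
  d3 <- centroid_displacements(pred, gt, max_link_dist = 15)
  expect_equal(sort(d$displacements_um), sort(d3$displacements_um))
})

test_that("nuclear area statistics carry units and match analytic areas", {
  labs <- matrix(0L, 32, 32); labs[5:14, 5:14] <- 1L
  st <- nuclear_area_stats(label_map(labs, um_per_px = 2))
  expect_equal(st$areas_px2, 100)
  expect_equal(st$areas_um2, 400)
  sc <- generate_scene(noiseless_spec(field = c(256L, 256L), n_cells = 16L,
                                      seed = 2))
  img <- render_fluorescence(sc, "nuclei")
  lm <- segment_nuclei(img, seg_config(blur_sigma = 2))
  st2 <- nuclear_area_stats(lm, outlier_rule = "none")
  expect_lt(abs(st2$summary$mean - mean(sc$truth$nucleus_area)) /
              mean(sc$truth$nucleus_area), 0.10)
})

test_that("junction-derived cell areas respect analytic bounds on a grid", {
  # 4x4 grid of square cells of side 32 drawn as 1-px bright lines
  img <- matrix(400, 128, 128)
  lines <- c(1, 33, 65, 97, 128)
  img[lines, ] <- 60000; img[, lines] <- 60000
  ca <- cell_areas_from_junctions(img, exclude_border = FALSE)
  inner <- ca$areas$area
  expect_equal(length(inner), 16)
  # skeleton keeps the 1-px line; one dilation erodes each cell by ~1 px more
  expect_true(all(inner >= (32 - 4)^2 & inner <= (32 - 2)^2))
  # conservation: areas + boundary pixels tile the frame
  expect_equal(sum(ca$areas$area) + ca$boundary_pixels, 128 * 128)
  # border exclusion with a flush grid keeps only interior cells
  img2 <- matrix(400, 128, 128)
  lines2 <- c(33, 65, 97)                      # grid flush to the frame edge
  img2[lines2, ] <- 60000; img2[, lines2] <- 60000
  ca2 <- cell_areas_from_junctions(img2, exclude_border = TRUE)
  expect_equal(nrow(ca2$areas), 4)             # only fully interior cells
  blank <- cell_areas_from_junctions(matrix(100, 64, 64),
                                     exclude_border = FALSE)
  expect_equal(nrow(blank$areas), 1)
  expect_equal(blank$areas$area, 64 * 64)
})

test_that("junction pipeline gives similar areas for truth and noisy copy", {
  sc <- generate_scene(noiseless_spec(field = c(256L, 256L), n_cells = 16L,
                                      seed = 6))
  jimg <- render_fluorescence(sc, "junctions")
  set.seed(8)
  noisy <- pmin(pmax(jimg + matrix(rnorm(length(jimg), 0, 500),
                                   nrow(jimg)), 0), 65535)
  a1 <- cell_areas_from_junctions(jimg)
  a2 <- cell_areas_from_junctions(noisy)
  expect_gt(nrow(a1$areas), 0)
  expect_lt(abs(mean(a1$areas$area) - mean(a2$areas$area)) /
              mean(a1$areas$area), 0.15)
})

test_that("line profiles interpolate bilinearly", {
  img <- matrix(runif(64 * 64, 0, 100), 64, 64)
  expect_equal(line_profile(img, c(10, 1), c(10, 64)), img[10, ])
  const <- matrix(7, 32, 32)
  expect_equal(line_profile(const, c(1, 1), c(32, 32)),
               rep(7, 45), tolerance = 1e-12)
  ramp <- matrix(seq_len(64), 64, 64)            # linear in the row index
  prof <- line_profile(ramp, c(1, 1), c(64, 64))
  expect_lt(max(abs(diff(prof) - diff(prof)[1])), 1e-6)
  expect_error(line_profile(img, c(0, 1), c(10, 10)), "out of bounds")
})
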