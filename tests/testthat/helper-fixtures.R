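# Shared fixtures, generated in code. The small noiseless dataset used by the
# training tests is built once per session and memoized.

noiseless_spec <- function(field = c(128L, 128L), n_cells = 9L, seed = 1L) {
  scene_spec(field_size = field, n_cells = n_cells,
             noise = list(gaussian_sd = 0, poisson_gain = 0, blur_sigma = 0),
             seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- make_dataset(noiseless_spec(), n_frames = 12L,
                                       seed = 5L, tile_size = 64L)
  }
  .fixture_env$small
}

# A tiny fitted model shared by prediction/stitching tests (fast to train).
tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- frm_fit(
      small_dataset(), loss = "mse",
      net_config = unet_config(64L, depth = 2L, base_filters = 4L),
      batch_size = 8L, max_epochs = 5L, seed = 11L)
  }
  .fixture_env$model
}

# Matrix with a filled disc of the given radius.
disc_image <- function(h, w, center, radius, fg = 10000, bg = 200) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  m <- matrix(bg, h, w)
  m[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- fg
  m
}
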