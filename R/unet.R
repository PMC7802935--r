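#' U-Net architecture configuration
#'
#' Describes the encoder--decoder network used for image-to-image regression:
#' `depth` encoder levels of two 3x3 same-padded convolutions + ReLU followed
#' by 2x2 max pooling, a bottleneck, and a mirrored decoder using 2x2
#' transposed-convolution upsampling with skip concatenation at each level.
#' A linear 1x1 convolution produces the output, so the network maps an
#' `input_size` x `input_size` single-channel tile to an output tile of
#' identical spatial dimensions.
#'
#' @param input_size Tile side length in pixels; must be divisible by
#'   `2^depth` so pooling/upsampling round-trips exactly.
#' @param depth Number of encoder (and decoder) levels.
#' @param base_filters Number of filters at the first level; doubles per level.
#' @param kernel Convolution kernel size (odd).
#' @param output_channels Number of predicted fluorescence channels.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_size = 256L, depth = 4L, base_filters = 64L,
                        kernel = 3L, output_channels = 1L) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (kernel %% 2L != 1L) stop("kernel size must be odd")
  if (input_size %% (2L^depth) != 0L)
    stop("input_size (", input_size, ") must be divisible by 2^depth (",
         2L^depth, ")")
  structure(list(input_size = input_size, depth = depth,
                 base_filters = as.integer(base_filters),
                 kernel = as.integer(kernel),
                 output_channels = as.integer(output_channels),
                 output_activation = "linear"),
            class = "unet_config")
}

he_init <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  array(stats::rnorm(k * k * cin * cout, 0, sd), c(k, k, cin, cout))
}

#' Build (initialize) a U-Net
#'
#' Allocates all convolution weights (He-normal, seeded through R's RNG) and
#' zero biases for the architecture described by `cfg`.
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet` holding the parameter list.
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k <- cfg$kernel
  nf <- cfg$base_filters * 2L^(0:cfg$depth)
  enc <- vector("list", cfg$depth)
  cin <- 1L
  for (l in seq_len(cfg$depth)) {
    f <- nf[l]
    enc[[l]] <- list(
      conv1 = list(w = he_init(k, cin, f), b = numeric(f)),
      conv2 = list(w = he_init(k, f, f), b = numeric(f)))
    cin <- f
  }
  fb <- nf[cfg$depth + 1L]
  bott <- list(conv1 = list(w = he_init(k, cin, fb), b = numeric(fb)),
               conv2 = list(w = he_init(k, fb, fb), b = numeric(fb)))
  dec <- vector("list", cfg$depth)
  cin <- fb
  for (l in rev(seq_len(cfg$depth))) {
    f <- nf[l]
    dec[[l]] <- list(
      up    = list(w = he_init(2L, cin, f), b = numeric(f)),
      conv1 = list(w = he_init(k, 2L * f, f), b = numeric(f)),
      conv2 = list(w = he_init(k, f, f), b = numeric(f)))
    cin <- f
  }
  outl <- list(w = he_init(1L, nf[1], cfg$output_channels),
               b = numeric(cfg$output_channels))
  structure(list(cfg = cfg, enc = enc, bottleneck = bott, dec = dec,
                 out = outl), class = "unet")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Number of trainable parameters
#' @param net A `unet` object.
#' @return Integer parameter count (deterministic for a given configuration).
#' @export
n_params <- function(net) {
  sum(vapply(unet_flatten(net), length, numeric(1)))
}

# Flatten the nested parameter lists into a named list of tensors (used by the
# optimizer); unet_unflatten inverts it.
unet_flatten <- function(net) {
  out <- list()
  for (l in seq_along(net$enc)) for (cv in c("conv1", "conv2"))
    for (p in c("w", "b"))
      out[[paste0("enc", l, ".", cv, ".", p)]] <- net$enc[[l]][[cv]][[p]]
  for (cv in c("conv1", "conv2")) for (p in c("w", "b"))
    out[[paste0("bott.", cv, ".", p)]] <- net$bottleneck[[cv]][[p]]
  for (l in seq_along(net$dec)) for (cv in c("up", "conv1", "conv2"))
    for (p in c("w", "b"))
      out[[paste0("dec", l, ".", cv, ".", p)]] <- net$dec[[l]][[cv]][[p]]
  for (p in c("w", "b")) out[[paste0("out.", p)]] <- net$out[[p]]
  out
}

unet_unflatten <- function(net, flat) {
  for (l in seq_along(net$enc)) for (cv in c("conv1", "conv2"))
    for (p in c("w", "b"))
      net$enc[[l]][[cv]][[p]] <- flat[[paste0("enc", l, ".", cv, ".", p)]]
  for (cv in c("conv1", "conv2")) for (p in c("w", "b"))
    net$bottleneck[[cv]][[p]] <- flat[[paste0("bott.", cv, ".", p)]]
  for (l in seq_along(net$dec)) for (cv in c("up", "conv1", "conv2"))
    for (p in c("w", "b"))
      net$dec[[l]][[cv]][[p]] <- flat[[paste0("dec", l, ".", cv, ".", p)]]
  for (p in c("w", "b")) net$out[[p]] <- flat[[paste0("out.", p)]]
  net
}

relu <- function(a) { a[a < 0] <- 0; a }

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Forward pass over a batch x[H,W,1,N]; returns prediction and (optionally)
# the activation cache needed for backprop.
unet_forward <- function(net, x, keep_cache = FALSE) {
  depth <- net$cfg$depth
  cache <- if (keep_cache) list(enc = vector("list", depth),
                                dec = vector("list", depth)) else NULL
  h <- x
  skips <- vector("list", depth)
  for (l in seq_len(depth)) {
    e <- net$enc[[l]]
    z1 <- .conv_fwd(h, e$conv1$w, e$conv1$b); a1 <- relu(z1)
    z2 <- .conv_fwd(a1, e$conv2$w, e$conv2$b); a2 <- relu(z2)
    pl <- .pool_fwd(a2)
    if (keep_cache)
      cache$enc[[l]] <- list(x = h, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                             idx = pl$idx)
    skips[[l]] <- a2
    h <- pl$y
  }
  bz1 <- .conv_fwd(h, net$bottleneck$conv1$w, net$bottleneck$conv1$b)
  ba1 <- relu(bz1)
  bz2 <- .conv_fwd(ba1, net$bottleneck$conv2$w, net$bottleneck$conv2$b)
  ba2 <- relu(bz2)
  if (keep_cache)
    cache$bott <- list(x = h, z1 = bz1, a1 = ba1, z2 = bz2, a2 = ba2)
  h <- ba2
  for (l in rev(seq_len(depth))) {
    d <- net$dec[[l]]
    u <- .upconv_fwd(h, d$up$w, d$up$b)
    cc <- cat_ch(skips[[l]], u)
    z1 <- .conv_fwd(cc, d$conv1$w, d$conv1$b); a1 <- relu(z1)
    z2 <- .conv_fwd(a1, d$conv2$w, d$conv2$b); a2 <- relu(z2)
    if (keep_cache)
      cache$dec[[l]] <- list(x = h, u = u, cc = cc, z1 = z1, a1 = a1,
                             z2 = z2, a2 = a2)
    h <- a2
  }
  y <- .conv_fwd(h, net$out$w, net$out$b)  # linear regression head
  if (keep_cache) { cache$head_in <- h; list(y = y, cache = cache) }
  else y
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter, given
# dL/dy. Returns a flat named list aligned with unet_flatten().
unet_backward <- function(net, cache, dy) {
  depth <- net$cfg$depth
  g <- list()
  bo <- .conv_bwd(cache$head_in, net$out$w, dy)
  g[["out.w"]] <- bo$dw; g[["out.b"]] <- bo$db
  dh <- bo$dx
  for (l in seq_len(depth)) {    # decoder, deepest-last order = l ascending
    d <- net$dec[[l]]; cc <- cache$dec[[l]]
    dz2 <- dh * (cc$z2 > 0)
    b2 <- .conv_bwd(cc$a1, d$conv2$w, dz2)
    dz1 <- b2$dx * (cc$z1 > 0)
    b1 <- .conv_bwd(cc$cc, d$conv1$w, dz1)
    nsk <- dim(cache$enc[[l]]$a2)[3]
    dskip <- b1$dx[, , seq_len(nsk), , drop = FALSE]
    du <- b1$dx[, , nsk + seq_len(dim(cc$u)[3]), , drop = FALSE]
    bu <- .upconv_bwd(cc$x, d$up$w, du)
    g[[paste0("dec", l, ".conv2.w")]] <- b2$dw
    g[[paste0("dec", l, ".conv2.b")]] <- b2$db
    g[[paste0("dec", l, ".conv1.w")]] <- b1$dw
    g[[paste0("dec", l, ".conv1.b")]] <- b1$db
    g[[paste0("dec", l, ".up.w")]] <- bu$dw
    g[[paste0("dec", l, ".up.b")]] <- bu$db
    cache$dec[[l]]$dskip <- dskip
    dh <- bu$dx
  }
  cb <- cache$bott
  dz2 <- dh * (cb$z2 > 0)
  b2 <- .conv_bwd(cb$a1, net$bottleneck$conv2$w, dz2)
  dz1 <- b2$dx * (cb$z1 > 0)
  b1 <- .conv_bwd(cb$x, net$bottleneck$conv1$w, dz1)
  g[["bott.conv2.w"]] <- b2$dw; g[["bott.conv2.b"]] <- b2$db
  g[["bott.conv1.w"]] <- b1$dw; g[["bott.conv1.b"]] <- b1$db
  dh <- b1$dx
  for (l in rev(seq_len(depth))) {
    e <- net$enc[[l]]; ce <- cache$enc[[l]]
    H <- dim(ce$a2)[1]; W <- dim(ce$a2)[2]
    da2 <- .pool_bwd(dh, ce$idx, H, W) + cache$dec[[l]]$dskip
    dz2 <- da2 * (ce$z2 > 0)
    b2 <- .conv_bwd(ce$a1, e$conv2$w, dz2)
    dz1 <- b2$dx * (ce$z1 > 0)
    b1 <- .conv_bwd(ce$x, e$conv1$w, dz1)
    g[[paste0("enc", l, ".conv2.w")]] <- b2$dw
    g[[paste0("enc", l, ".conv2.b")]] <- b2$db
    g[[paste0("enc", l, ".conv1.w")]] <- b1$dw
    g[[paste0("enc", l, ".conv1.b")]] <- b1$db
    dh <- b1$dx
  }
  g
}

# Raw network inference on a 3-d array of tiles (H,W,N) in normalized units.
unet_predict_tiles <- function(net, tiles, batch_size = 16L) {
  d <- dim(tiles)
  out <- array(0, d)
  i <- 1L
  while (i <= d[3]) {
    j <- min(i + batch_size - 1L, d[3])
    xb <- array(tiles[, , i:j], c(d[1], d[2], 1L, j - i + 1L))
    yb <- unet_forward(net, xb)
    out[, , i:j] <- yb[, , 1L, ]
    i <- j + 1L
  }
  out
}
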