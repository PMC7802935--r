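#' Fit a fluorescence-reconstruction U-Net
#'
#' Trains an image-to-image U-Net to predict a fluorescence channel from
#' transmitted-light tiles. Tiles are z-normalized with statistics pooled over
#' the training partition of each channel; optimization uses ADADELTA on
#' minibatches, under either the mean-squared-error loss or the
#' Pearson-correlation loss `(1 - PCC)^2`. Early stopping monitors the
#' validation loss with a strict-decrease criterion: when it has not decreased
#' for `patience` epochs (default 75) training terminates and the weights of
#' the best epoch are restored.
#'
#' @param data An [tile_dataset()] with non-empty `train` and `validation`
#'   partitions.
#' @param loss `"mse"` or `"pcc"`.
#' @param net_config A [unet_config()] matching the tile size.
#' @param batch_size Minibatch size (default 16).
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs (default 75).
#' @param early_stopping Set `FALSE` to train for exactly `max_epochs`
#'   (used by the epoch-sweep harness).
#' @param augment `"none"`, or `"full"` for 5x offline 45-degree rotations
#'   plus online flip/zoom augmentation of each training batch.
#' @param rho,epsilon,learning_rate ADADELTA hyperparameters.
#' @param seed Integer seed covering weight initialization, batch shuffling
#'   and augmentation draws.
#' @param log_csv Optional path; per-epoch losses are appended as CSV.
#' @param verbose Print per-epoch progress.
#' @return An object of class `frm_model`: the trained network, the
#'   normalization statistics of both channels, and the training history
#'   (`epoch`, `train_loss`, `val_loss`, `seconds`) with `best_epoch` and
#'   `stopped_epoch`.
#' @seealso [predict.frm_model()], [plot.frm_model()]
#' @export
frm_fit <- function(data, loss = c("mse", "pcc"),
                    net_config = unet_config(input_size = dim(data$x)[1]),
                    batch_size = 16L, max_epochs = 100L, patience = 75L,
                    early_stopping = TRUE, augment = c("none", "full"),
                    rho = 0.95, epsilon = 1e-7, learning_rate = 1.0,
                    seed = 1L, log_csv = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "frm_tiles"))
  loss <- match.arg(loss)
  augment <- match.arg(augment)
  if (patience < 1 || max_epochs < 1) stop("patience and max_epochs must be >= 1")
  tr <- tiles_in_split(data, "train")
  va <- tiles_in_split(data, "validation")
  if (dim(tr$x)[3] == 0) stop("empty training partition")
  if (dim(va$x)[3] == 0) stop("empty validation partition")

  norm_in <- compute_norm_stats(tr$x)
  norm_out <- compute_norm_stats(tr$y)
  if (norm_in$degenerate || norm_out$degenerate)
    stop("degenerate statistics: a channel has zero variance on the training set")
  xt <- normalize_tiles(tr$x, norm_in); yt <- normalize_tiles(tr$y, norm_out)
  xv <- normalize_tiles(va$x, norm_in); yv <- normalize_tiles(va$y, norm_out)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (augment == "full") {
    aug <- augment_offline_rotations(xt, yt,
                                     seed = sample.int(.Machine$integer.max, 1))
    xt <- aug$x; yt <- aug$y
  }
  net <- build_unet(net_config, seed = sample.int(.Machine$integer.max, 1))
  opt <- adadelta_init(unet_flatten(net))
  n_train <- dim(xt)[3]
  H <- dim(xt)[1]; W <- dim(xt)[2]

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), seconds = numeric())
  best_val <- Inf; best_epoch <- 0L; best_flat <- NULL; wait <- 0L
  degenerate_batches <- 0L
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    t0 <- proc.time()[["elapsed"]]
    perm <- sample.int(n_train)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n_train, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n_train)]
      B <- length(idx)
      xb <- array(0, c(H, W, 1L, B)); yb <- array(0, c(H, W, 1L, B))
      for (q in seq_len(B)) {
        xi <- xt[, , idx[q]]; yi <- yt[, , idx[q]]
        if (augment == "full") {
          a <- augment_online(xi, yi)
          xi <- a$x; yi <- a$y
        }
        xb[, , 1L, q] <- xi; yb[, , 1L, q] <- yi
      }
      fw <- unet_forward(net, xb, keep_cache = TRUE)
      lg <- loss_grad(loss, fw$y, yb)
      if (!is.finite(lg$value))
        stop("non-finite training loss at epoch ", epoch, "; aborting")
      if (lg$degenerate) degenerate_batches <- degenerate_batches + 1L
      grads <- unet_backward(net, fw$cache, lg$grad)
      flat <- unet_flatten(net)
      flat <- adadelta_step(flat, grads, opt, rho, epsilon, learning_rate)
      net <- unet_unflatten(net, flat)
      ep_loss <- ep_loss + lg$value; nb <- nb + 1L
    }
    val_pred <- unet_predict_tiles(net, xv[, , , drop = FALSE], batch_size)
    vl <- if (loss == "mse") mse_loss(val_pred, yv)
          else as.numeric(pcc_loss(val_pred, yv))
    if (!is.finite(vl)) stop("non-finite validation loss at epoch ", epoch)
    secs <- proc.time()[["elapsed"]] - t0
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / nb,
                                         val_loss = vl, seconds = secs))
    if (!is.null(log_csv))
      utils::write.csv(history, log_csv, row.names = FALSE)
    if (verbose)
      message(sprintf("epoch %d  train %.5f  val %.5f  (%.1fs)",
                      epoch, ep_loss / nb, vl, secs))
    if (vl < best_val) {
      best_val <- vl; best_epoch <- epoch; wait <- 0L
      if (early_stopping) best_flat <- unet_flatten(net)
    } else wait <- wait + 1L
    if (early_stopping && wait >= patience) break
  }
  if (early_stopping && !is.null(best_flat))
    net <- unet_unflatten(net, best_flat)
  if (!early_stopping) best_epoch <- epoch
  structure(list(net = net, net_config = net_config, loss = loss,
                 norm_in = norm_in, norm_out = norm_out, channel = data$channel,
                 history = history, best_epoch = best_epoch,
                 stopped_epoch = epoch,
                 degenerate_batches = degenerate_batches,
                 augment = augment, seed = as.integer(seed),
                 call = match.call()),
            class = "frm_model")
}

adadelta_init <- function(flat) {
  e <- new.env(parent = emptyenv())
  e$Eg2 <- lapply(flat, function(p) p * 0)
  e$Edx2 <- lapply(flat, function(p) p * 0)
  e
}

# One ADADELTA update over every parameter tensor.
adadelta_step <- function(flat, grads, opt, rho, epsilon, lr) {
  for (nm in names(flat)) {
    g <- grads[[nm]]
    opt$Eg2[[nm]] <- rho * opt$Eg2[[nm]] + (1 - rho) * g^2
    dx <- -sqrt(opt$Edx2[[nm]] + epsilon) / sqrt(opt$Eg2[[nm]] + epsilon) * g
    opt$Edx2[[nm]] <- rho * opt$Edx2[[nm]] + (1 - rho) * dx^2
    flat[[nm]] <- flat[[nm]] + lr * dx
  }
  flat
}

#' @export
print.frm_model <- function(x, ...) {
  cat("Fluorescence reconstruction U-Net (channel: ", x$channel, ")\n",
      sep = "")
  cat(sprintf("  tiles %dx%d, depth %d, base filters %d (%s parameters)\n",
              x$net_config$input_size, x$net_config$input_size,
              x$net_config$depth, x$net_config$base_filters,
              format(n_params(x$net), big.mark = ",")))
  cat(sprintf("  loss: %s; trained %d epoch(s), best epoch %d (val loss %.5f)\n",
              x$loss, x$stopped_epoch, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.frm_model <- function(object, ...) {
  h <- object$history
  structure(list(model = object,
                 n_epochs = nrow(h),
                 best_epoch = object$best_epoch,
                 best_val = h$val_loss[object$best_epoch],
                 final_train = h$train_loss[nrow(h)],
                 total_seconds = sum(h$seconds),
                 n_parameters = n_params(object$net)),
            class = "summary.frm_model")
}

#' @export
print.summary.frm_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  final training loss %.5f; %.1f s total (%d parameters)\n",
              x$final_train, x$total_seconds, x$n_parameters))
  invisible(x)
}

#' Training-history plot
#'
#' Training and validation loss per epoch, with the best (restored) epoch
#' marked.
#' @param x An `frm_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.frm_model <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = paste0(x$loss, " loss"), ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Predict fluorescence from transmitted light
#'
#' For `type = "tile"`, `newdata` is a matrix or `(H, W, N)` array of tiles
#' matching the network input size; each tile is normalized with the model's
#' input statistics, passed through the network, and de-normalized with the
#' fluorescence channel's statistics. For `type = "image"`, `newdata` is an
#' arbitrarily sized image (or multi-page list) reconstructed with the
#' sliding-window procedure of [sliding_window_predict()].
#'
#' @param object An `frm_model`.
#' @param newdata Matrix, 3-d array of tiles, or list of matrices (timelapse).
#' @param type `"tile"` or `"image"`.
#' @param stitch A [stitch_config()] (image mode).
#' @param clamp Clamp de-normalized output to the valid count range
#'   `[0, 65535]` (default `TRUE` for image mode, `FALSE` for tiles).
#' @param ... Unused.
#' @return Predicted fluorescence in counts, same spatial shape as the input.
#' @export
predict.frm_model <- function(object, newdata, type = c("tile", "image"),
                              stitch = stitch_config(
                                window = object$net_config$input_size),
                              clamp = (type[1] == "image"), ...) {
  type <- match.arg(type)
  if (type == "tile") {
    single <- is.matrix(newdata)
    tiles <- if (single) array(newdata, c(dim(newdata), 1L)) else newdata
    stopifnot(dim(tiles)[1] == object$net_config$input_size,
              dim(tiles)[2] == object$net_config$input_size)
    z <- normalize_tiles(tiles, object$norm_in)
    p <- unet_predict_tiles(object$net, z)
    p <- denormalize(p, object$norm_out)
    if (clamp) p <- pmin(pmax(p, 0), 65535)
    if (single) p[, , 1L] else p
  } else {
    if (is.list(newdata))
      predict_timelapse(object, newdata, cfg = stitch, clamp = clamp)
    else
      sliding_window_predict(object, newdata, cfg = stitch, clamp = clamp)
  }
}

#' Held-out residuals
#'
#' Prediction minus ground truth (in counts) over the tiles of a chosen
#' partition of a dataset.
#' @param object An `frm_model`.
#' @param data An `frm_tiles` dataset.
#' @param split Partition to evaluate (default `"test"`).
#' @param ... Unused.
#' @return `(H, W, N)` array of residuals.
#' @export
residuals.frm_model <- function(object, data, split = "test", ...) {
  te <- tiles_in_split(data, split)
  predict(object, te$x, type = "tile") - te$y
}
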