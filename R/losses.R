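#' Mean-squared-error loss
#'
#' Mean over all pixels of the squared difference between prediction and
#' ground truth.
#'
#' @param pred,truth Numeric arrays of identical dimensions (a tile, or a
#'   batch of tiles).
#' @return A single number, >= 0 and 0 iff `pred == truth`.
#' @export
mse_loss <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical dimensions")
  mean((pred - truth)^2)
}

#' Pearson-correlation loss
#'
#' `Loss = (1 - PCC)^2`, with the Pearson correlation coefficient pooled over
#' every pixel of the batch. The loss lies in \[0, 4\]: 0 for perfect
#' correlation, 1 for uncorrelated signals, 4 for perfect anticorrelation.
#' Because PCC is invariant to positive affine rescaling of either argument,
#' so is this loss.
#'
#' When either signal has zero variance the correlation is undefined; the
#' loss then falls back to 1 (the uncorrelated value) and carries attribute
#' `degenerate = TRUE`, so optimization never sees a non-finite value.
#'
#' @inheritParams mse_loss
#' @return A single number in \[0, 4\] (attribute `degenerate` flags the
#'   zero-variance fallback).
#' @export
pcc_loss <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have identical dimensions")
  a <- as.numeric(truth) - mean(truth)
  b <- as.numeric(pred) - mean(pred)
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0)
    return(structure(1, degenerate = TRUE))
  r <- sum(a * b) / sqrt(na2 * nb2)
  (1 - r)^2
}

# Loss value and gradient w.r.t. pred, for the optimizer.
loss_grad <- function(loss, pred, truth) {
  if (loss == "mse") {
    d <- pred - truth
    list(value = mean(d^2), grad = 2 * d / length(d), degenerate = FALSE)
  } else {
    a <- truth - mean(truth)
    b <- pred - mean(pred)
    na2 <- sum(a^2); nb2 <- sum(b^2)
    if (na2 == 0 || nb2 == 0)
      return(list(value = 1, grad = array(0, dim(pred)), degenerate = TRUE))
    na <- sqrt(na2); nb <- sqrt(nb2)
    r <- sum(a * b) / (na * nb)
    drdb <- a / (na * nb) - r * b / nb2
    list(value = (1 - r)^2, grad = -2 * (1 - r) * drdb, degenerate = FALSE)
  }
}
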