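#' Evaluate a fitted model on a dataset partition
#'
#' Predicts every tile of the chosen partition and scores the predictions
#' against ground truth with the corrected accuracy score P.
#'
#' @param model An `frm_model`.
#' @param data An `frm_tiles` dataset.
#' @param cfg A [metric_config()].
#' @param split Partition to score (default `"test"`).
#' @return The [accuracy_score_P()] report.
#' @export
frm_evaluate <- function(model, data, cfg = metric_config(),
                         split = "test") {
  te <- tiles_in_split(data, split)
  if (dim(te$x)[3] == 0) stop("partition '", split, "' is empty")
  pred <- predict(model, te$x, type = "tile")
  accuracy_score_P(te$y, pred, cfg)
}

# Clone a dataset keeping validation/test but replacing the train partition
# with the given tile indices.
subset_train <- function(data, train_idx) {
  keep <- data$meta$split != "train"
  sel <- keep | seq_len(nrow(data$meta)) %in% train_idx
  out <- data
  out$x <- data$x[, , sel, drop = FALSE]
  out$y <- data$y[, , sel, drop = FALSE]
  out$meta <- data$meta[sel, , drop = FALSE]
  out
}

#' Training-set-size sweep
#'
#' For each fraction and replicate, samples that fraction of the training
#' tiles (without replacement, replicate-indexed seed), trains a fresh model
#' from scratch with unchanged hyperparameters, and scores the accuracy P on
#' the fixed original test set -- the scaling experiment relating
#' reconstruction quality to training-set size.
#'
#' @param data An `frm_tiles` dataset.
#' @param fractions Ascending fractions of the training set in `(0, 1]`.
#' @param replicates Fresh models per fraction (default 3).
#' @param seed Master seed.
#' @param metric A [metric_config()] for scoring.
#' @param ... Passed to [frm_fit()] (loss, epochs, network size, ...).
#' @return Data frame `(fraction, replicate, n_images, P, raw_pcc)`.
#' @export
run_size_sweep <- function(data, fractions = c(1 / 16, 1 / 4, 1),
                           replicates = 3L, seed = 1L,
                           metric = metric_config(), ...) {
  stopifnot(!is.unsorted(fractions), all(fractions > 0 & fractions <= 1))
  train_idx <- which(data$meta$split == "train")
  rows <- list()
  for (fi in seq_along(fractions)) {
    n_sub <- max(1L, round(fractions[fi] * length(train_idx)))
    for (rep in seq_len(replicates)) {
      cell_seed <- as.integer((seed * 1009 + fi * 101 + rep) %% 2147483647)
      old <- .Random.seed_save()
      set.seed(cell_seed)
      sub <- sample(train_idx, n_sub)
      .Random.seed_restore(old)
      d <- subset_train(data, sub)
      fit <- frm_fit(d, seed = cell_seed, ...)
      rep_report <- frm_evaluate(fit, d, metric)
      rows[[length(rows) + 1L]] <-
        data.frame(fraction = fractions[fi], replicate = rep,
                   n_images = n_sub, P = rep_report$P$mean,
                   raw_pcc = rep_report$raw$mean)
    }
  }
  do.call(rbind, rows)
}

#' Training-epoch sweep
#'
#' Trains a fresh model from scratch for each exact epoch budget in the grid
#' (early stopping disabled), `replicates` per condition, scoring P on the
#' fixed test set and logging the wall-clock time.
#'
#' @param data An `frm_tiles` dataset.
#' @param epoch_grid Integer epoch budgets.
#' @param replicates Fresh models per budget.
#' @param seed Master seed.
#' @param metric A [metric_config()].
#' @param ... Passed to [frm_fit()].
#' @return Data frame `(epochs, replicate, P, train_seconds)`.
#' @export
run_epoch_sweep <- function(data, epoch_grid = c(1L, 5L, 20L),
                            replicates = 3L, seed = 1L,
                            metric = metric_config(), ...) {
  rows <- list()
  for (ei in seq_along(epoch_grid)) {
    for (rep in seq_len(replicates)) {
      cell_seed <- as.integer((seed * 1013 + ei * 103 + rep) %% 2147483647)
      fit <- frm_fit(data, max_epochs = epoch_grid[ei],
                     early_stopping = FALSE, seed = cell_seed, ...)
      rep_report <- frm_evaluate(fit, data, metric)
      rows[[length(rows) + 1L]] <-
        data.frame(epochs = epoch_grid[ei], replicate = rep,
                   P = rep_report$P$mean,
                   train_seconds = sum(fit$history$seconds))
    }
  }
  do.call(rbind, rows)
}

#' Paired MSE-versus-PCC loss comparison
#'
#' Trains two networks that differ only in the loss function (identical
#' architecture, data and seed) and scores both on the shared test set.
#'
#' @param data An `frm_tiles` dataset.
#' @param seed Shared seed for both arms.
#' @param metric A [metric_config()].
#' @param ... Passed to [frm_fit()] (everything except `loss`).
#' @return Data frame `(loss, P, raw_pcc)` with one row per arm.
#' @export
compare_losses <- function(data, seed = 1L, metric = metric_config(), ...) {
  do.call(rbind, lapply(c("mse", "pcc"), function(l) {
    fit <- frm_fit(data, loss = l, seed = seed, ...)
    rep_report <- frm_evaluate(fit, data, metric)
    data.frame(loss = l, P = rep_report$P$mean, raw_pcc = rep_report$raw$mean)
  }))
}
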