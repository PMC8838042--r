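#' Split pairs into train / test / validation sets
#'
#' Seeded shuffle followed by a disjoint, exhaustive partition: the test and
#' validation sizes are the rounded fractions and the remainder goes to
#' train.
#'
#' @param pairs Non-empty list of [sample_pair]s.
#' @param fractions `(train, test, validation)` fractions summing to 1.
#' @param seed Integer seed fixing membership.
#' @return A named list `train`, `test`, `validation`.
#' @examples
#' ds <- generate_dataset(20, synth_config(height = 64, width = 64))
#' lengths(split_dataset(ds$pairs, c(0.7, 0.15, 0.15), seed = 1))
#' @export
split_dataset <- function(pairs, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(pairs) == 0) stop("empty pair list", call. = FALSE)
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            all(fractions > 0))
  n <- length(pairs)
  n_test <- round(n * fractions[2])
  n_val <- round(n * fractions[3])
  n_train <- n - n_test - n_val
  if (n_train < 1 || n_test < 1 || n_val < 1)
    stop("split produces an empty subset (n = ", n, ", sizes ",
         n_train, "/", n_test, "/", n_val, ")", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ord <- sample.int(n)
  list(train = pairs[ord[seq_len(n_train)]],
       test = pairs[ord[n_train + seq_len(n_test)]],
       validation = pairs[ord[n_train + n_test + seq_len(n_val)]])
}

#' Enumerate a hyperparameter grid
#'
#' The full published grid — three optimizers, batch sizes 8/18/32, epoch
#' budgets 25/50/75/100 — enumerates 36 cells.
#'
#' @param optimizers Character vector of optimizer names.
#' @param batch_sizes Integer vector.
#' @param epochs Integer vector.
#' @return A tibble with one row per `(optimizer, batch_size, epochs)` cell.
#' @examples
#' nrow(sweep_grid(c("adam", "sgd", "adadelta"), c(8, 18, 32), c(25, 50, 75, 100)))
#' @export
sweep_grid <- function(optimizers = c("adam", "sgd", "adadelta"),
                       batch_sizes = c(8L, 18L, 32L),
                       epochs = c(25L, 50L, 75L, 100L)) {
  stopifnot(length(optimizers) > 0, length(batch_sizes) > 0,
            length(epochs) > 0)
  tidyr::expand_grid(optimizer = optimizers,
                     batch_size = as.integer(batch_sizes),
                     epochs = as.integer(epochs))
}

#' Optimizer x batch-size x epochs sweep harness
#'
#' Mirrors the published experimental design: one model is trained per grid
#' cell from an identical initialization seed, evaluated on all three splits,
#' and the best cell is the validation-accuracy argmax. Augmentation (per
#' `base_config$augment_recipe`) is applied to the training split only,
#' after splitting, so no augmented copy of a test or validation frame can
#' leak into training.
#'
#' @param pairs Full list of [sample_pair]s (split internally).
#' @param spec A `unet_spec`.
#' @param optimizers,batch_sizes,epochs Grid axes (see [sweep_grid()]).
#' @param base_config A [train_config()] supplying everything the grid does
#'   not vary (seed, split fractions, threshold, augmentation recipe).
#' @param verbose Log one line per cell.
#' @return An object of class `unet_sweep`: list with `rows` (one metric row
#'   per config x split, reporting scale as in [evaluate_split()]), `best`
#'   (the winning config), `histories` (per-cell training curves), `grid`,
#'   and `splits` (the split membership sizes).
#' @export
sweep_architectures <- function(pairs, spec,
                                optimizers = "adam",
                                batch_sizes = 8L,
                                epochs = 10L,
                                base_config = train_config(),
                                verbose = FALSE) {
  grid <- sweep_grid(optimizers, batch_sizes, epochs)
  splits <- split_dataset(pairs, base_config$split, seed = base_config$seed)
  train_pairs <- splits$train
  if (length(base_config$augment_recipe) > 0)
    train_pairs <- expand_dataset(train_pairs, base_config$augment_recipe,
                                  seed = base_config$seed)
  rows <- list(); histories <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$optimizer <- grid$optimizer[g]
    cfg$learning_rate <- switch(cfg$optimizer,
                                adam = 1e-3, sgd = 1e-2, adadelta = 1.0)
    cfg$batch_size <- grid$batch_size[g]
    cfg$epochs <- grid$epochs[g]
    if (verbose)
      message("cell ", g, "/", nrow(grid), ": ", cfg$optimizer,
              ", batch ", cfg$batch_size, ", ", cfg$epochs, " epochs")
    fit <- train_unet(train_pairs, NULL, spec, cfg)
    histories[[g]] <- dplyr::mutate(fit$history,
                                    optimizer = cfg$optimizer,
                                    batch_size = cfg$batch_size,
                                    epochs = cfg$epochs, .before = 1)
    for (sp in names(splits)) {
      m <- evaluate_split(splits[[sp]], fit$network,
                          threshold = cfg$threshold)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        optimizer = cfg$optimizer, batch_size = cfg$batch_size,
        epochs = cfg$epochs, learning_rate = cfg$learning_rate,
        seed = cfg$seed, split = sp,
        jaccard = m$jaccard, dice = m$dice, precision = m$precision,
        recall = m$recall, accuracy = m$accuracy, loss = m$loss)
    }
  }
  rows <- dplyr::bind_rows(rows)
  structure(list(rows = rows,
                 best = best_sweep_cell(rows),
                 histories = dplyr::bind_rows(histories),
                 grid = grid,
                 split_sizes = lengths(splits)),
            class = "unet_sweep")
}

#' Select the best sweep cell by validation accuracy
#'
#' @param rows The metric rows of a sweep (or a `unet_sweep`).
#' @return The single winning row (validation split, maximum accuracy; first
#'   row on ties).
#' @export
best_sweep_cell <- function(rows) {
  if (inherits(rows, "unet_sweep")) rows <- rows$rows
  val <- rows[rows$split == "validation", ]
  val[which.max(val$accuracy), ]
}

#' @export
print.unet_sweep <- function(x, ...) {
  cat("<unet_sweep> ", nrow(x$grid), " cells x 3 splits\n", sep = "")
  b <- x$best
  cat("  best (validation accuracy): ", b$optimizer, ", batch ",
      b$batch_size, ", ", b$epochs, " epochs -> ",
      sprintf("%.2f%%", b$accuracy), "\n", sep = "")
  invisible(x)
}

#' @rdname sweep_architectures
#' @param x A `unet_sweep`.
#' @export
tidy.unet_sweep <- function(x, ...) x$rows

#' @rdname sweep_architectures
#' @export
glance.unet_sweep <- function(x, ...) x$best

#' Threshold a prediction and zero the background
#'
#' Produces the two visual outputs of a segmenter: the binarized predicted
#' mask and the segmented overlay, i.e. the input image with every
#' background pixel set to zero.
#'
#' @param network A `unet_network`, `unet_fit`, or probability-map function.
#' @param image An `H x W x 3` image in `[0, 1]` (or a [sample_pair]).
#' @param threshold Binarization threshold.
#' @return A list with `prob` (probability matrix), `mask` (binary matrix)
#'   and `overlay` (`H x W x 3` array).
#' @export
predict_and_overlay <- function(network, image, threshold = 0.5) {
  if (inherits(image, "sample_pair")) image <- image$image
  if (inherits(network, "unet_fit")) network <- network$network
  prob <- if (inherits(network, "unet_network")) predict(network, image)
          else network(image)
  mask <- 1 * (prob >= threshold)
  overlay <- image * as.vector(mask)   # mask recycles over the 3 channels
  list(prob = prob, mask = mask, overlay = overlay)
}

#' Write sweep results and training histories as CSV
#'
#' @param sweep A `unet_sweep`.
#' @param rows_path Output CSV for the metric rows (reporting column order).
#' @param history_path Optional output CSV for per-epoch curves.
#' @return `rows_path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, rows_path, history_path = NULL) {
  write_metric_rows(sweep$rows, rows_path, format = "csv")
  if (!is.null(history_path))
    readr::write_csv(sweep$histories, history_path)
  invisible(rows_path)
}
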