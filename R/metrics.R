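#' Pixel confusion counts for a binary mask pair
#'
#' Tallies true/false positives and negatives between a predicted and a
#' ground-truth lesion mask (1 = lesion, 0 = background).
#'
#' @param pred,truth Binary matrices (or arrays) of identical shape with
#'   values strictly in `{0, 1}`.
#' @return A one-row tibble of class `confusion_counts` with columns `tp`,
#'   `fp`, `fn`, `tn`; the four always sum to the pixel count.
#' @examples
#' confusion_counts(matrix(c(1, 1, 0, 1), 2), matrix(c(1, 0, 1, 1), 2))
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), call. = FALSE)
  check_binary <- function(m, nm) {
    bad <- m[m != 0 & m != 1]
    if (length(bad) > 0)
      stop(nm, " mask is not binary: contains value ", format(bad[1]),
           call. = FALSE)
  }
  check_binary(pred, "pred")
  check_binary(truth, "truth")
  tp <- sum(pred * truth)
  fp <- sum(pred) - tp
  fn <- sum(truth) - tp
  tn <- length(pred) - tp - fp - fn
  structure(tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn),
            class = c("confusion_counts", class(tibble::tibble())))
}

#' Overlap and accuracy scores from confusion counts
#'
#' Computes Jaccard index, Dice coefficient, precision, recall and pixel
#' accuracy, each as a fraction in `[0, 1]`. With `smooth = 0` the standard
#' definitions apply and the Dice-Jaccard identity `D = 2J / (1 + J)` holds;
#' a positive `smooth` is added to numerator and denominator of the overlap
#' scores (the usual stabilizer for empty masks). The empty-vs-empty case
#' (`tp = fp = fn = 0`) returns 1 for Jaccard and Dice by convention; a
#' 0/0 precision or recall is returned as `NA` with `flagged = TRUE`.
#'
#' @param counts A `confusion_counts` row (or any list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @param smooth Non-negative smoothing constant (default 0 = standard).
#' @return A one-row tibble of class `metric_report` with columns `jaccard`,
#'   `dice`, `precision`, `recall`, `accuracy`, `flagged`.
#' @examples
#' overlap_scores(confusion_counts(matrix(1, 2, 2), matrix(1, 2, 2)))
#' @export
overlap_scores <- function(counts, smooth = 0) {
  if (smooth < 0) stop("smooth must be non-negative", call. = FALSE)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  flagged <- FALSE
  denom_j <- tp + fp + fn + smooth
  jaccard <- if (denom_j == 0) 1 else (tp + smooth) / denom_j
  denom_d <- 2 * tp + fp + fn + smooth
  dice <- if (denom_d == 0) 1 else (2 * tp + smooth) / denom_d
  precision <- if (tp + fp == 0) { flagged <- TRUE; NA_real_ } else tp / (tp + fp)
  recall <- if (tp + fn == 0) { flagged <- TRUE; NA_real_ } else tp / (tp + fn)
  accuracy <- (tp + tn) / (tp + fp + fn + tn)
  structure(tibble::tibble(jaccard = jaccard, dice = dice,
                           precision = precision, recall = recall,
                           accuracy = accuracy, flagged = flagged),
            class = c("metric_report", class(tibble::tibble())))
}

#' Soft (probability-input) overlap scores
#'
#' Overlap computed directly on a probability map without binarization:
#' `intersection = sum(p * y)`, `soft_dice = (2 I + s) / (sum p + sum y + s)`,
#' `soft_jaccard = (I + s) / (sum p + sum y - I + s)`. On a binary `p` with
#' `smooth = 0` these equal the standard scores.
#'
#' @param pred_prob Probability map in `[0, 1]`, same shape as `truth`.
#' @param truth Binary mask.
#' @param smooth Non-negative smoothing constant.
#' @return A one-row tibble with `soft_jaccard` and `soft_dice`.
#' @export
soft_overlap <- function(pred_prob, truth, smooth = 0) {
  if (!identical(dim(pred_prob), dim(truth)))
    stop("shapes differ: ", paste(dim(pred_prob), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), call. = FALSE)
  if (smooth < 0) stop("smooth must be non-negative", call. = FALSE)
  if (any(pred_prob < 0) || any(pred_prob > 1))
    stop("pred_prob contains values outside [0, 1]", call. = FALSE)
  inter <- sum(pred_prob * truth)
  sp <- sum(pred_prob); st <- sum(truth)
  dj <- sp + st - inter + smooth
  dd <- sp + st + smooth
  tibble::tibble(
    soft_jaccard = if (dj == 0) 1 else (inter + smooth) / dj,
    soft_dice = if (dd == 0) 1 else (2 * inter + smooth) / dd)
}

#' Evaluate a segmenter on a dataset split
#'
#' Predicts a probability map per pair, binarizes at `threshold`, accumulates
#' confusion counts per the aggregation mode, and reports the six scores on
#' the conventional reporting scale: Jaccard, Dice, precision, recall and
#' accuracy as percentages, loss as 100 x mean binary cross-entropy.
#' `per_image_mean` averages per-image scores; `global_pixels` pools the
#' pixel counts of the whole split into one confusion matrix first.
#'
#' @param pairs Non-empty list of [sample_pair] objects.
#' @param network A `unet_network`, a `unet_fit`, or a plain function mapping
#'   an `H x W x 3` image to an `H x W` probability matrix (useful as an
#'   oracle in tests).
#' @param aggregation `"per_image_mean"` (default) or `"global_pixels"`.
#' @param threshold Binarization threshold in (0, 1).
#' @param smooth Smoothing constant forwarded to [overlap_scores()].
#' @return A one-row tibble of class `metric_report` with columns `jaccard`,
#'   `dice`, `precision`, `recall`, `accuracy` (percent), `loss`
#'   (100 x nats), `flagged`, `n_images`, `aggregation`.
#' @export
evaluate_split <- function(pairs, network,
                           aggregation = c("per_image_mean", "global_pixels"),
                           threshold = 0.5, smooth = 0) {
  aggregation <- rlang::arg_match(aggregation)
  if (length(pairs) == 0) stop("empty pair list", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(network, "unet_fit")) network <- network$network
  probs <- if (inherits(network, "unet_network")) {
    predict(network, pairs)
  } else {
    lapply(pairs, function(p) network(p$image))
  }
  losses <- numeric(length(pairs))
  counts <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    y <- pairs[[i]]$mask
    p <- probs[[i]]
    losses[i] <- bce_loss(p, y)
    counts[[i]] <- confusion_counts(1 * (p >= threshold), y)
  }
  if (aggregation == "global_pixels") {
    tot <- dplyr::summarise(dplyr::bind_rows(counts),
                            dplyr::across(dplyr::everything(), sum))
    sc <- overlap_scores(tot, smooth = smooth)
  } else {
    per <- dplyr::bind_rows(lapply(counts, overlap_scores, smooth = smooth))
    sc <- dplyr::summarise(per,
                           dplyr::across(c("jaccard", "dice", "precision",
                                           "recall", "accuracy"),
                                         ~ mean(.x, na.rm = TRUE)),
                           flagged = any(.data$flagged))
  }
  structure(tibble::tibble(jaccard = 100 * sc$jaccard, dice = 100 * sc$dice,
                           precision = 100 * sc$precision,
                           recall = 100 * sc$recall,
                           accuracy = 100 * sc$accuracy,
                           loss = 100 * mean(losses),
                           flagged = sc$flagged,
                           n_images = length(pairs),
                           aggregation = aggregation),
            class = c("metric_report", class(tibble::tibble())))
}

#' Serialize metric rows in the reporting column order
#'
#' Writes rows keyed by `(split, optimizer, batch_size, epochs)` followed by
#' Jaccard, Dice, precision, recall, accuracy and loss, as CSV or JSON.
#'
#' @param rows A tibble of metric rows (e.g. `tidy()` of a sweep).
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_metric_rows <- function(rows, path, format = c("csv", "json")) {
  format <- rlang::arg_match(format)
  lead <- intersect(c("split", "optimizer", "batch_size", "epochs",
                      "learning_rate", "seed"), names(rows))
  metric <- intersect(c("jaccard", "dice", "precision", "recall",
                        "accuracy", "loss"), names(rows))
  rows <- rows[, c(lead, metric, setdiff(names(rows), c(lead, metric)))]
  if (format == "csv") readr::write_csv(rows, path)
  else jsonlite::write_json(rows, path, digits = NA, pretty = TRUE)
  invisible(path)
}
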