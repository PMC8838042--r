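#' Plot training curves of a fitted network
#'
#' Loss and pixel accuracy per epoch, one panel each.
#'
#' @param object A `unet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("%s, batch %d", object$config$optimizer,
                                  object$config$batch_size)) +
    ggplot2::theme_minimal()
}

#' Plot sweep results across configurations
#'
#' One bar per configuration and split for the chosen metric.
#'
#' @param object A `unet_sweep`.
#' @param metric Column to plot (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unet_sweep <- function(object, metric = "accuracy", ...) {
  rows <- dplyr::mutate(object$rows,
                        config = paste0(.data$optimizer, "/b",
                                        .data$batch_size, "/e", .data$epochs))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$config,
                                     y = .data[[metric]],
                                     fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Display an image/mask pair
#'
#' Image, ground-truth mask, and their overlay as three raster panels.
#'
#' @param object A [sample_pair].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_pair <- function(object, ...) {
  h <- nrow(object$mask); w <- ncol(object$mask)
  px <- tidyr::expand_grid(col = seq_len(w), row = seq_len(h))  # row fastest,
  # matching R's column-major vectorization of the image planes
  as_rgb <- function(img) grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  panels <- dplyr::bind_rows(
    dplyr::mutate(px, fill = as_rgb(object$image), panel = "image"),
    dplyr::mutate(px, fill = grDevices::gray(as.vector(object$mask)),
                  panel = "mask"),
    dplyr::mutate(px, fill = as_rgb(object$image *
                                      as.vector(object$mask)),
                  panel = "overlay"))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(title = object$sample_id, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
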