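#' Plot bootstrap metrics with their intervals
#'
#' @param object A `boot_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boot_metrics <- function(object, ...) {
  t <- as_tibble(object)
  ggplot2::ggplot(
    t,
    ggplot2::aes(x = .data$metric, y = .data$mean,
      ymin = .data$lower, ymax = .data$upper)
  ) +
    ggplot2::geom_pointrange() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "bootstrap mean (95% interval)",
      title = sprintf("Ensemble performance (B = %d)", attr(object, "B"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model's development-AUC trajectory
#'
#' @param object A `face_model`.
#' @param ... Unused.
#' @return A ggplot with the selected checkpoint marked.
#' @export
autoplot.face_model <- function(object, ...) {
  t <- object$trajectory
  ggplot2::ggplot(t, ggplot2::aes(.data$epoch, .data$dev_auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$phase))) +
    ggplot2::geom_vline(
      xintercept = object$selected_epoch, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "epoch", y = "development ROC AUC", shape = "phase",
      title = paste("Training trajectory:", object$backbone$name)
    ) +
    ggplot2::theme_minimal()
}

#' Display rendered face frames
#'
#' @param frameset A frame-set or image-set tibble with an `image`
#'   list-column.
#' @param n Maximum number of frames to show.
#' @return A ggplot raster grid, one facet per frame.
#' @export
plot_frames <- function(frameset, n = 6) {
  frameset <- head(frameset, n)
  yaw <- frameset$yaw %||% frameset$target_yaw
  long <- purrr::map_dfr(seq_len(nrow(frameset)), function(i) {
    img <- frameset$image[[i]]
    tibble(
      panel = sprintf("%s @ %.0f deg", frameset$participant_id[i], yaw[i]),
      row = rep(seq_len(nrow(img)), times = ncol(img)),
      col = rep(seq_len(ncol(img)), each = nrow(img)),
      value = as.vector(img)
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
}

#' Plot an agreement decomposition
#'
#' @param object An [agreement_table()].
#' @param ... Unused.
#' @return A ggplot bar chart of overlap regions per class.
#' @export
autoplot.agreement_table <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$region, y = .data$count)
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "correctly classified by", y = "participants",
      title = "Agreement of predictors"
    ) +
    ggplot2::theme_minimal()
}
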