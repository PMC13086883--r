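#' Kaplan-Meier step curves
#'
#' @param km per-arm Kaplan-Meier tibble (the `$km` element of an
#'   `rfs_report`, or any tibble with `arm`, `time`, `estimate`).
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  km0 <- dplyr::bind_rows(
    dplyr::distinct(km, .data$arm) |>
      dplyr::mutate(time = 0, estimate = 1),
    km[, c("arm", "time", "estimate")]
  )
  ggplot2::ggplot(km0, ggplot2::aes(.data$time, .data$estimate,
                                    colour = .data$arm)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since diagnosis",
                  y = "Recurrence-free survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_km
#' @param object an `rfs_report`.
#' @param ... unused.
#' @export
autoplot.rfs_report <- function(object, ...) plot_km(object$km)

#' ROC curve of per-patient scores
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  thr <- sort(unique(c(-Inf, object$scores, Inf)), decreasing = TRUE)
  pts <- dplyr::bind_rows(lapply(thr, function(t) {
    tibble(fpr = mean(object$scores[object$labels == 0] >= t),
           tpr = mean(object$scores[object$labels == 1] >= t))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f [%.3f-%.3f]", object$auc, object$ci_low,
                      object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Grad-CAM heatmap over the source slice
#'
#' Renders the saliency map, optionally blended over a grayscale underlay
#' of one channel of the source slice.
#'
#' @param object a `grad_cam_map`.
#' @param underlay optional 64 x 64 matrix (e.g. one phase of the scored
#'   slice) drawn in grayscale beneath the heatmap.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.grad_cam_map <- function(object, underlay = NULL, ...) {
  df <- expand.grid(row = seq_len(nrow(object$heatmap)),
                    col = seq_len(ncol(object$heatmap)))
  df$cam <- as.vector(object$heatmap)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row))
  if (!is.null(underlay)) {
    df$under <- as.vector(underlay)
    p <- p + ggplot2::geom_raster(ggplot2::aes(alpha = .data$under),
                                  fill = "grey10") +
      ggplot2::scale_alpha(range = c(0, 1), guide = "none")
  }
  p + ggplot2::geom_raster(ggplot2::aes(fill = .data$cam),
                           alpha = if (is.null(underlay)) 1 else 0.5) +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "Grad-CAM",
                  title = sprintf("p(NHG3-like) = %.2f", object$prob)) +
    ggplot2::theme_void()
}

#' Training-loss curve
#'
#' @param loss_history numeric per-epoch loss (from [train_cnn()]).
#' @return A ggplot object.
#' @export
plot_loss <- function(loss_history) {
  df <- tibble(epoch = seq_along(loss_history), loss = loss_history)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Weighted BCE loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
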