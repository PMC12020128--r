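# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-step training history of a dual-branch fit
#'
#' @param x a `dual_branch_fit`
#' @param ... unused
#' @return tibble with `step`, `lr`, `loss`, `det_loss`, `seg_loss`
#' @method tidy dual_branch_fit
#' @export
tidy.dual_branch_fit <- function(x, ...) x$history

#' One-row summary of a dual-branch fit
#'
#' @param x a `dual_branch_fit`
#' @param ... unused
#' @return tibble with step count and final loss components
#' @method glance dual_branch_fit
#' @export
glance.dual_branch_fit <- function(x, ...) {
  last <- dplyr::slice_tail(x$history, n = 1)
  tibble::tibble(steps = nrow(x$history), loss = last$loss,
                 det_loss = last$det_loss, seg_loss = last$seg_loss)
}

#' Tidy a continual-adaptation result
#'
#' @param x a `domain_sequence_result`
#' @param ... unused
#' @return the per-domain metric tibble
#' @method tidy domain_sequence_result
#' @export
tidy.domain_sequence_result <- function(x, ...) x$per_domain

#' Stream-average metrics of a continual-adaptation result
#'
#' @param x a `domain_sequence_result`
#' @param ... unused
#' @return one-row tibble of metric means over domains
#' @method glance domain_sequence_result
#' @export
glance.domain_sequence_result <- function(x, ...) x$average

#' Plot the training loss curves of a dual-branch fit
#'
#' @param object a `dual_branch_fit`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot dual_branch_fit
#' @export
autoplot.dual_branch_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(step = h$step, loss = h$det_loss, component = "detection"),
    tibble::tibble(step = h$step, loss = h$seg_loss, component = "segmentation"),
    tibble::tibble(step = h$step, loss = h$loss, component = "total"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-domain mAP50 along the adaptation stream
#'
#' @param object a `domain_sequence_result`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot domain_sequence_result
#' @export
autoplot.domain_sequence_result <- function(object, ...) {
  d <- object$per_domain
  d$domain <- factor(d$domain, levels = unique(d$domain))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$domain, y = .data$map50,
                                  group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$average$map50,
                        linetype = "dashed") +
    ggplot2::labs(x = "domain (stream order)", y = "mAP50") +
    ggplot2::theme_minimal()
}

#' Plot a labeled scene with its boxes (and optional predictions)
#'
#' @param scene a [labeled_scene()]
#' @param pred optional [detections()] drawn in a second colour
#' @return a ggplot object
#' @export
plot_scene <- function(scene, pred = NULL) {
  d <- dim(scene$image)
  px <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  px$fill <- grDevices::rgb(scene$image[, , 1], scene$image[, , 2],
                            scene$image[, , 3])
  boxes_df <- function(b, who) {
    if (nrow(b) == 0) return(NULL)
    tibble::tibble(xmin = b[, 1], ymin = b[, 2], xmax = b[, 3],
                   ymax = b[, 4], who = who)
  }
  bx <- dplyr::bind_rows(boxes_df(scene$boxes, "truth"),
                         if (!is.null(pred)) boxes_df(pred$boxes, "pred"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = px,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         fill = px$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(bx) && nrow(bx)) {
    p <- p + ggplot2::geom_rect(
      data = bx,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$who),
      fill = NA, linewidth = 0.4)
  }
  p
}

#' @importFrom rlang .data
NULL
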