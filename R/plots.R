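# ggplot2 views of scenes and results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic scene's geometry
#'
#' Tooth outlines with CEJ-bone regions filled by their true bone-loss
#' percentage, in image coordinates (y increases downward).
#'
#' @param object A `"periobone_scene"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot periobone_scene
#' @export
autoplot.periobone_scene <- function(object, ...) {
  polys <- scene_polys(object)
  truth <- scene_truth(object)
  poly_df <- function(p, id, kind, side = NA_character_) {
    tibble::tibble(x = p[, 1L], y = p[, 2L], tooth_id = id,
                   kind = kind, side = side,
                   group = paste(id, kind, side))
  }
  teeth_df <- purrr::map_dfr(polys, ~ poly_df(.x$tooth, .x$tooth_id, "tooth"))
  reg_df <- purrr::map_dfr(polys, function(p) {
    dplyr::bind_rows(poly_df(p$mesial, p$tooth_id, "region", "mesial"),
                     poly_df(p$distal, p$tooth_id, "region", "distal"))
  })
  reg_df <- dplyr::left_join(reg_df, truth, by = c("tooth_id", "side"))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = teeth_df,
                          ggplot2::aes(.data$x, .data$y, group = .data$group),
                          fill = "grey85", colour = "grey30") +
    ggplot2::geom_polygon(data = reg_df,
                          ggplot2::aes(.data$x, .data$y, group = .data$group,
                                       fill = .data$true_percent),
                          colour = NA) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "true bone loss (%)",
                                  limits = c(0, 100)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Synthetic dental scene") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-tooth bone loss with prognosis
#'
#' Highlights the tooth with the greatest loss, mirroring the usual
#' per-tooth percentage overlay on analyzed radiographs.
#'
#' @param results Classified per-tooth tibble (see [classify_dentition()]).
#' @return A ggplot.
#' @export
plot_bone_loss <- function(results) {
  worst <- greatest_loss(results)
  df <- dplyr::mutate(results,
                      is_worst = .data$tooth_id == worst$tooth_id[[1L]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tooth_id,
                                   y = .data$percent_bone_loss,
                                   fill = .data$prognosis)) +
    ggplot2::geom_col(ggplot2::aes(colour = .data$is_worst), linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = NA),
                                 guide = "none") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = 1,
                               drop = FALSE) +
    ggplot2::labs(x = "tooth (FDI)", y = "bone loss (%)",
                  title = "Per-tooth alveolar bone loss",
                  subtitle = sprintf("greatest loss: tooth %s (%.1f%%)",
                                     worst$tooth_id[[1L]],
                                     worst$percent_bone_loss[[1L]])) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Precision-recall curve at a fixed IoU threshold
#'
#' @inheritParams average_precision
#' @return A ggplot of the PR staircase with its precision envelope.
#' @export
plot_precision_recall <- function(predictions, ground_truth,
                                  iou_threshold = 0.5) {
  if (!"label" %in% names(predictions)) predictions$label <- "object"
  if (!"label" %in% names(ground_truth)) ground_truth$label <- "object"
  curves <- purrr::map_dfr(sort(unique(ground_truth$label)), function(lb) {
    pr <- pr_curve_one_class(
      predictions[predictions$label == lb, , drop = FALSE],
      ground_truth[ground_truth$label == lb, , drop = FALSE], iou_threshold)
    dplyr::mutate(pr, label = lb)
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$recall, .data$precision,
                                       colour = .data$label)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope), linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Precision-recall at IoU %.2f", iou_threshold)) +
    ggplot2::theme_minimal()
}

pr_curve_one_class <- function(predictions, ground_truth, iou_threshold) {
  ng <- nrow(ground_truth)
  np <- nrow(predictions)
  if (np == 0L) {
    return(tibble::tibble(recall = 0, precision = 1, envelope = 1))
  }
  ord <- order(-predictions$confidence, seq_len(np))
  gt_taken <- rep(FALSE, ng)
  is_tp <- logical(np)
  for (k in seq_along(ord)) {
    i <- ord[k]
    ious <- vapply(seq_len(ng), function(j)
      poly_iou(predictions$points[[i]], ground_truth$points[[j]]), numeric(1))
    cand <- which(!gt_taken & ious >= iou_threshold)
    if (length(cand)) {
      gt_taken[cand[which.max(ious[cand])]] <- TRUE
      is_tp[k] <- TRUE
    }
  }
  tp_cum <- cumsum(is_tp)
  fp_cum <- cumsum(!is_tp)
  precision <- tp_cum / (tp_cum + fp_cum)
  tibble::tibble(recall = tp_cum / ng, precision = precision,
                 envelope = rev(cummax(rev(precision))))
}
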