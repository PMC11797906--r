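# Detection evaluation: polygon IoU, greedy confidence-ordered matching,
# cell-grid confusion matrices (the unit that makes true negatives
# countable), threshold metrics, average precision at IoU 0.5, and the
# train/validation/test split.

#' Intersection over union of two polygons
#'
#' Exact area ratio `area(a intersect b) / area(a union b)` via polygon
#' clipping; 0 for disjoint shapes, 1 for identical ones.
#'
#' @param a,b Simple polygons (n x 2 matrices).
#' @return A scalar in `[0, 1]`.
#' @export
poly_iou <- function(a, b) {
  aa <- polygon_area(a)
  ab <- polygon_area(b)
  if (aa <= 0 || ab <= 0) stop("zero-area polygon in IoU", call. = FALSE)
  inter <- poly_intersection_area(a, b)
  inter / (aa + ab - inter)
}

#' Greedy one-to-one matching of detections to ground truth
#'
#' Predictions are visited in descending confidence; each is matched to the
#' not-yet-matched ground-truth polygon with the highest IoU at or above the
#' threshold (ties toward the lowest ground-truth index; confidence ties
#' toward the lowest prediction index). Leftover predictions are false
#' positives, leftover ground truths false negatives.
#'
#' @param predictions Tibble with `points` (list of polygons) and
#'   `confidence`.
#' @param ground_truth Tibble with `points` (list of polygons).
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return A list of class `"detection_matches"`: `matches` tibble
#'   (`pred_id`, `gt_id`, `iou`, `confidence`), `unmatched_pred` and
#'   `unmatched_gt` integer vectors.
#' @export
match_detections <- function(predictions, ground_truth, iou_threshold = 0.5) {
  np <- nrow(predictions); ng <- nrow(ground_truth)
  iou_mat <- matrix(0, np, ng)
  if (np && ng) {
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) {
        iou_mat[i, j] <- poly_iou(predictions$points[[i]], ground_truth$points[[j]])
      }
    }
  }
  order_pred <- if (np) order(-predictions$confidence, seq_len(np)) else integer()
  gt_taken <- rep(FALSE, ng)
  rows <- list()
  for (i in order_pred) {
    cand <- which(!gt_taken & iou_mat[i, ] >= iou_threshold)
    if (!length(cand)) next
    j <- cand[which.max(iou_mat[i, cand])]
    gt_taken[j] <- TRUE
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pred_id = i, gt_id = j, iou = iou_mat[i, j],
      confidence = predictions$confidence[[i]])
  }
  matches <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pred_id = integer(), gt_id = integer(),
                   iou = numeric(), confidence = numeric())
  structure(list(
    matches = matches,
    unmatched_pred = setdiff(seq_len(np), matches$pred_id),
    unmatched_gt = setdiff(seq_len(ng), matches$gt_id)
  ), class = "detection_matches")
}

#' Build an evaluation grid over an image
#'
#' Tiles the frame into square cells and records, per cell, whether any
#' ground-truth and any predicted polygon covers the cell center. The grid
#' is the countable evaluation unit behind the pixel-region confusion
#' matrices (object-level matching has no true negatives).
#'
#' @inheritParams match_detections
#' @param image_width,image_height Frame size in pixels.
#' @param cell_size Cell edge, pixels (default 64).
#' @return Tibble of class `"eval_grid"`: `cell_x`, `cell_y`, `gt`, `pred`
#'   logicals, one row per cell (`ceiling(w/cell) * ceiling(h/cell)` rows).
#' @export
make_eval_grid <- function(predictions, ground_truth, image_width, image_height,
                           cell_size = 64) {
  stopifnot(cell_size >= 1)
  nx <- ceiling(image_width / cell_size)
  ny <- ceiling(image_height / cell_size)
  centers <- expand.grid(
    cell_x = seq_len(nx) - 1L,
    cell_y = seq_len(ny) - 1L
  )
  cx <- (centers$cell_x + 0.5) * cell_size
  cy <- (centers$cell_y + 0.5) * cell_size
  pts <- cbind(cx, cy)
  covered <- function(polys) {
    hit <- rep(FALSE, nrow(pts))
    for (p in polys) hit <- hit | points_in_polygon(pts, p)
    hit
  }
  out <- tibble::tibble(
    cell_x = centers$cell_x, cell_y = centers$cell_y,
    gt = covered(ground_truth$points),
    pred = covered(predictions$points)
  )
  class(out) <- c("eval_grid", class(out))
  attr(out, "cell_size") <- cell_size
  out
}

#' Confusion matrix from an evaluation grid
#'
#' Per cell: ground truth and prediction both present is a true positive,
#' prediction only a false positive, ground truth only a false negative,
#' neither a true negative. Counts sum to the number of cells.
#'
#' @param grid An `"eval_grid"` tibble, or any data frame with logical
#'   `gt` and `pred` columns.
#' @return A `"confusion_matrix"` object (list with `tp`, `fp`, `fn`, `tn`).
#' @export
confusion_from_grid <- function(grid) {
  confusion_matrix(
    tp = sum(grid$gt & grid$pred),
    fp = sum(!grid$gt & grid$pred),
    fn = sum(grid$gt & !grid$pred),
    tn = sum(!grid$gt & !grid$pred)
  )
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A `"confusion_matrix"` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows: predicted, cols: actual)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(c("positive", "negative"),
                              c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Threshold metrics from a confusion matrix
#'
#' Precision, sensitivity (recall), specificity, accuracy and F1. Ratios
#' with a zero denominator are reported as `NA`, never coerced to 0.
#'
#' @param cm A `"confusion_matrix"`.
#' @return One-row tibble: `precision`, `sensitivity`, `specificity`,
#'   `accuracy`, `f1`.
#' @export
#' @examples
#' detection_metrics(confusion_matrix(tp = 508, fp = 234, fn = 11, tn = 17877))
detection_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty evaluation: all confusion counts are zero",
                       call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  sensitivity <- ratio(cm$tp, cm$tp + cm$fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  tibble::tibble(
    precision = precision,
    sensitivity = sensitivity,
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    accuracy = (cm$tp + cm$tn) / total,
    f1 = f1
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion matrix into long counts
#'
#' @param x A `"confusion_matrix"`.
#' @param ... Unused.
#' @return Tibble with `cell` (tp/fp/fn/tn) and `count`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "fn", "tn"),
                 count = c(x$tp, x$fp, x$fn, x$tn))
}

#' One-row metric summary of a confusion matrix
#'
#' @inheritParams tidy.confusion_matrix
#' @return The [detection_metrics()] tibble with total count appended.
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  dplyr::mutate(detection_metrics(x), n_units = x$tp + x$fp + x$fn + x$tn)
}

#' Average precision at a fixed IoU threshold
#'
#' Sweeps the precision-recall curve over the confidence ranking with
#' IoU-threshold matching and integrates the area under the precision
#' envelope (all-point interpolation). With a `label` column on both inputs,
#' AP is computed per class and the mean over classes (mAP) is returned in
#' the `mean_ap` attribute.
#'
#' @inheritParams match_detections
#' @return Tibble with `label` and `ap`; attribute `mean_ap` holds the mean
#'   over classes (mAP50 for the default threshold).
#' @export
average_precision <- function(predictions, ground_truth, iou_threshold = 0.5) {
  if (nrow(ground_truth) == 0L) {
    stop("empty evaluation: no ground-truth objects", call. = FALSE)
  }
  if (!"label" %in% names(predictions)) predictions$label <- "object"
  if (!"label" %in% names(ground_truth)) ground_truth$label <- "object"
  labels <- sort(unique(ground_truth$label))
  ap <- vapply(labels, function(lb) {
    ap_one_class(predictions[predictions$label == lb, , drop = FALSE],
                 ground_truth[ground_truth$label == lb, , drop = FALSE],
                 iou_threshold)
  }, numeric(1))
  out <- tibble::tibble(label = labels, ap = unname(ap))
  attr(out, "mean_ap") <- mean(ap)
  out
}

ap_one_class <- function(predictions, ground_truth, iou_threshold) {
  ng <- nrow(ground_truth)
  if (ng == 0L) return(NA_real_)
  np <- nrow(predictions)
  if (np == 0L) return(0)
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
  recall <- tp_cum / ng
  precision <- tp_cum / (tp_cum + fp_cum)
  # precision envelope (non-increasing from the right), all-point area
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Deterministic train/validation/test split
#'
#' Shuffles the ids under a fixed seed and partitions them into shares of
#' the given ratios; validation and test sizes are the rounded shares and
#' the remainder goes to training. Partitions are disjoint and their union
#' is the input.
#'
#' @param ids Vector of identifiers.
#' @param ratios Length-3 numeric summing to 1 (default `c(0.7, 0.1, 0.2)`).
#' @param seed Integer seed for the shuffle.
#' @return Named list `train`, `validation`, `test`.
#' @export
#' @examples
#' lengths(split_dataset(1:2000, seed = 1))  # 1400 / 200 / 400
split_dataset <- function(ids, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9) {
    stop("split ratios must be three numbers summing to 1", call. = FALSE)
  }
  n <- length(ids)
  shuffled <- withr::with_seed(seed, sample(ids, n))
  n_val <- round(ratios[2L] * n)
  n_test <- round(ratios[3L] * n)
  n_train <- n - n_val - n_test
  list(
    train = shuffled[seq_len(n_train)],
    validation = shuffled[n_train + seq_len(n_val)],
    test = shuffled[n_train + n_val + seq_len(n_test)]
  )
}
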