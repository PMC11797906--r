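# Shared in-code fixtures: polygons, LabelMe files, random instances and
# brute-force oracles.

square_poly <- function(x0, y0, size) {
  cbind(x = c(x0, x0 + size, x0 + size, x0),
        y = c(y0, y0, y0 + size, y0 + size))
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Random convex polygon (angle-sorted points on a jittered circle), fully
# inside [margin, w - margin] x [margin, h - margin].
random_convex_poly <- function(w, h, n = 6, margin = 40) {
  cx <- runif(1, margin, w - margin)
  cy <- runif(1, margin, h - margin)
  r <- runif(1, 5, margin - 1)
  th <- sort(runif(n, 0, 2 * pi))
  rad <- r * runif(n, 0.6, 1)
  cbind(x = cx + rad * cos(th), y = cy + rad * sin(th))
}

annotation_tbl <- function(labels, polys, w, h) {
  tibble::tibble(label = labels, points = polys,
                 image_width = rep(w, length(polys)),
                 image_height = rep(h, length(polys)))
}

write_labelme_fixture <- function(path, shapes, w = 100, h = 100) {
  doc <- list(version = "5.0.0", shapes = shapes,
              imageHeight = h, imageWidth = w, imagePath = "x.png")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

shape_entry <- function(label, points, type = "polygon") {
  list(label = label,
       points = lapply(seq_len(nrow(points)), function(i) unname(points[i, ])),
       shape_type = type)
}

# Exhaustive one-to-one matcher: maximizes match count, then total IoU.
# Returns a sorted "pred:gt" pair set for comparison with the greedy result.
brute_force_match <- function(predictions, ground_truth, iou_threshold = 0.5) {
  np <- nrow(predictions); ng <- nrow(ground_truth)
  iou_mat <- matrix(0, max(np, 1L), max(ng, 1L))
  for (i in seq_len(np)) for (j in seq_len(ng)) {
    iou_mat[i, j] <- poly_iou(predictions$points[[i]], ground_truth$points[[j]])
  }
  best <- list(count = -1L, iou = -Inf, pairs = character())
  recurse <- function(i, taken, pairs, total) {
    if (i > np) {
      cnt <- length(pairs)
      if (cnt > best$count || (cnt == best$count && total > best$iou)) {
        best <<- list(count = cnt, iou = total, pairs = sort(pairs))
      }
      return(invisible())
    }
    recurse(i + 1L, taken, pairs, total)  # leave prediction i unmatched
    for (j in seq_len(ng)) {
      if (!taken[j] && iou_mat[i, j] >= iou_threshold) {
        taken[j] <- TRUE
        recurse(i + 1L, taken, c(pairs, sprintf("%d:%d", i, j)),
                total + iou_mat[i, j])
        taken[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), character(), 0)
  best$pairs
}

# Random near-diagonal detection instance: spaced ground-truth squares with
# jittered copies as predictions, plus optional far-away false positives.
random_match_instance <- function(max_objects = 6) {
  ng <- sample.int(max_objects, 1)
  gt <- tibble::tibble(
    points = lapply(seq_len(ng), function(j) square_poly(100 * j, 100, 40)))
  keep <- runif(ng) > 0.2
  pred_polys <- lapply(which(keep), function(j) {
    square_poly(100 * j + runif(1, -8, 8), 100 + runif(1, -8, 8), 40)
  })
  n_fp <- sample(0:2, 1)
  fp_polys <- lapply(seq_len(n_fp), function(k) {
    square_poly(100 * k, 300, 40)
  })
  pred <- tibble::tibble(points = c(pred_polys, fp_polys),
                         confidence = runif(length(pred_polys) + n_fp))
  list(pred = pred, gt = gt)
}

# Oracle-annotation bone-loss recovery for one scene; returns sites joined
# with the generating truth.
recover_scene <- function(scene) {
  ann <- oracle_annotations(scene)
  landmarks <- locate_landmarks(ann$teeth, ann$regions)
  sites <- measure_bone_loss(
    measure_sites(landmarks, ann$teeth, scene$mm_per_pixel),
    biologic_width_mm = scene$biologic_width_mm)
  dplyr::inner_join(sites, scene_truth(scene), by = c("tooth_id", "side"))
}

support_band <- function(support) {
  dplyr::case_when(
    support > 75 ~ "Good",
    support >= 50 ~ "Fair",
    support >= 25 ~ "Questionable",
    TRUE ~ "Hopeless"
  )
}
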