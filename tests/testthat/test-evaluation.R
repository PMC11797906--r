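# IoU, matching, grid confusion matrices, metrics, AP and the split.

test_that("polygon IoU matches analytic areas", {
  a <- square_poly(0, 0, 1)
  expect_equal(poly_iou(a, a), 1)
  expect_equal(poly_iou(a, square_poly(5, 5, 1)), 0)
  # unit squares overlapping half: 0.5 / 1.5
  expect_equal(poly_iou(a, square_poly(0.5, 0, 1)), 1 / 3, tolerance = 1e-7)
  flat <- cbind(c(0, 1, 2), c(0, 0, 0))
  expect_error(poly_iou(a, flat), "zero-area")
})

test_that("greedy matching follows confidence order and IoU ties", {
  gt <- tibble::tibble(points = list(square_poly(0, 0, 10)))
  pred <- tibble::tibble(
    points = list(square_poly(0, 0, 10), square_poly(1, 0, 10)),
    confidence = c(0.6, 0.9))
  m <- match_detections(pred, gt)
  # the 0.9-confidence prediction wins the only ground truth
  expect_identical(m$matches$pred_id, 2L)
  expect_identical(m$unmatched_pred, 1L)
  expect_identical(m$unmatched_gt, integer(0))

  exact <- match_detections(
    tibble::tibble(points = list(square_poly(0, 0, 10)), confidence = 1), gt)
  expect_identical(nrow(exact$matches), 1L)
  expect_equal(exact$matches$iou, 1)
})

test_that("greedy matching equals brute-force optimal on random instances", {
  set.seed(77)
  for (k in 1:100) {
    inst <- random_match_instance()
    got <- match_detections(inst$pred, inst$gt)
    got_pairs <- sort(sprintf("%d:%d", got$matches$pred_id, got$matches$gt_id))
    expect_identical(got_pairs, brute_force_match(inst$pred, inst$gt))
  }
})

test_that("grid confusion matrices count cells exactly", {
  empty <- make_eval_grid(tibble::tibble(points = list()),
                          tibble::tibble(points = list()), 40, 40,
                          cell_size = 10)
  cm0 <- confusion_from_grid(empty)
  expect_identical(cm0$tn, 16L)
  expect_identical(cm0$tp + cm0$fp + cm0$fn, 0L)

  gt <- tibble::tibble(points = list(rect_poly(0, 0, 20, 20)))
  same <- make_eval_grid(gt, gt, 40, 40, cell_size = 10)
  cm1 <- confusion_from_grid(same)
  expect_identical(c(cm1$fp, cm1$fn), c(0L, 0L))
  expect_identical(cm1$tp, 4L)

  # hand-counted 4x4 grid: GT covers cells x 0-1, pred covers x 1-2 (y 0-1)
  pred <- tibble::tibble(points = list(rect_poly(10, 0, 30, 20)))
  cm2 <- confusion_from_grid(make_eval_grid(pred, gt, 40, 40, cell_size = 10))
  expect_identical(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(2L, 2L, 2L, 10L))
  # conservation over random cases
  set.seed(8)
  for (k in 1:5) {
    g <- make_eval_grid(
      tibble::tibble(points = list(random_convex_poly(200, 200))),
      tibble::tibble(points = list(random_convex_poly(200, 200))),
      200, 190, cell_size = 32)
    cm <- confusion_from_grid(g)
    expect_identical(cm$tp + cm$fp + cm$fn + cm$tn,
                     as.integer(ceiling(200 / 32) * ceiling(190 / 32)))
  }
})

test_that("metrics reproduce the segmentation-model confusion arithmetic", {
  cej <- detection_metrics(confusion_matrix(tp = 508, fp = 234, fn = 11,
                                            tn = 17877))
  expect_equal(cej$accuracy, 18385 / 18630)
  expect_equal(round(cej$accuracy, 4), 0.9868)
  expect_equal(round(cej$specificity, 4), 0.9871)
  expect_equal(round(cej$sensitivity, 4), 0.9788)
  expect_equal(round(cej$precision, 4), 0.6846)
  expect_equal(cej$f1, 2 * cej$precision * cej$sensitivity /
                 (cej$precision + cej$sensitivity))

  teeth <- detection_metrics(confusion_matrix(tp = 983, fp = 589, fn = 11,
                                              tn = 18687))
  expect_equal(round(teeth$accuracy, 4), 0.9704)
  expect_equal(round(teeth$specificity, 4), 0.9694)
})

test_that("perfect and degenerate matrices behave at the edges", {
  perfect <- detection_metrics(confusion_matrix(10, 0, 0, 20))
  expect_true(all(unlist(perfect) == 1))
  nodet <- detection_metrics(confusion_matrix(0, 0, 5, 10))
  expect_true(is.na(nodet$precision))  # absent, not zero
  expect_equal(nodet$sensitivity, 0)
  expect_error(detection_metrics(confusion_matrix(0, 0, 0, 0)),
               "empty evaluation")
})

test_that("tidy and glance summarize confusion matrices", {
  cm <- confusion_matrix(508, 234, 11, 17877)
  td <- generics::tidy(cm)
  expect_identical(td$count[td$cell == "tn"], 17877)
  gl <- generics::glance(cm)
  expect_equal(gl$n_units, 18630)
  expect_equal(gl$accuracy, 18385 / 18630)
})

test_that("average precision integrates the hand-computed staircase", {
  gt <- tibble::tibble(points = lapply(1:5, function(j) square_poly(50 * j, 0, 20)))
  perfect <- tibble::tibble(points = gt$points, confidence = runif(5))
  ap1 <- average_precision(perfect, gt)
  expect_equal(attr(ap1, "mean_ap"), 1)

  none <- tibble::tibble(points = lapply(1:3, function(j) square_poly(50 * j, 500, 20)),
                         confidence = c(0.9, 0.8, 0.7))
  expect_equal(attr(average_precision(none, gt), "mean_ap"), 0)

  # 5 true detections with one false positive at mid confidence:
  # ranked TP TP TP FP TP TP -> AP = 0.6 + 0.4 * (5/6) = 14/15
  fixture <- tibble::tibble(
    points = c(gt$points, list(square_poly(0, 500, 20))),
    confidence = c(0.95, 0.9, 0.8, 0.6, 0.5, 0.7))
  expect_equal(attr(average_precision(fixture, gt), "mean_ap"), 14 / 15,
               tolerance = 1e-12)
  expect_error(average_precision(perfect, gt[0, ]), "no ground-truth")
})

test_that("AP is invariant to monotone confidence rescaling", {
  set.seed(31)
  gt <- tibble::tibble(points = lapply(1:4, function(j) square_poly(60 * j, 0, 30)))
  pred <- tibble::tibble(
    points = c(lapply(1:4, function(j) square_poly(60 * j + 5, 2, 30)),
               list(square_poly(10, 300, 30))),
    confidence = c(0.9, 0.7, 0.5, 0.3, 0.6))
  base <- attr(average_precision(pred, gt), "mean_ap")
  pred2 <- dplyr::mutate(pred, confidence = confidence^3 / 2)
  expect_equal(attr(average_precision(pred2, gt), "mean_ap"), base)
})

test_that("per-class AP averages into mAP", {
  gt <- tibble::tibble(points = list(square_poly(0, 0, 20), square_poly(100, 0, 20)),
                       label = c("tooth", "cej_bone_region"))
  pred <- tibble::tibble(points = list(square_poly(0, 0, 20), square_poly(300, 0, 20)),
                         label = c("tooth", "cej_bone_region"),
                         confidence = c(0.9, 0.8))
  ap <- average_precision(pred, gt)
  expect_identical(sort(ap$label), c("cej_bone_region", "tooth"))
  expect_equal(sort(ap$ap), c(0, 1))
  expect_equal(attr(ap, "mean_ap"), 0.5)
})

test_that("the 70:10:20 split is exact, disjoint and reproducible", {
  sp <- split_dataset(seq_len(2000), seed = 4)
  expect_identical(lengths(sp), c(train = 1400L, validation = 200L, test = 400L))
  expect_identical(sort(unname(unlist(sp))), seq_len(2000))
  expect_identical(split_dataset(letters[1:10], seed = 3),
                   split_dataset(letters[1:10], seed = 3))
  expect_false(identical(split_dataset(seq_len(100), seed = 1)$train,
                         split_dataset(seq_len(100), seed = 2)$train))
  expect_error(split_dataset(1:10, ratios = c(0.5, 0.2, 0.2)), "summing to 1")
})
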