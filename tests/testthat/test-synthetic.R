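# Scene generation, rendering, oracle annotations and perturbation.

test_that("scene generation is reproducible and validates layout", {
  s1 <- generate_scene(14, loss = "uniform", loss_range = c(0, 90), seed = 7)
  s2 <- generate_scene(14, loss = "uniform", loss_range = c(0, 90), seed = 7)
  expect_identical(s1$teeth, s2$teeth)
  expect_identical(nrow(s1$teeth), 14L)
  expect_true(all(grepl("^[34][1-8]$", s1$teeth$tooth_id)))

  healthy <- generate_scene(1, loss = "fixed", loss_value = 0, seed = 1)
  expect_equal(healthy$teeth$loss_mesial, 0)
  expect_equal(healthy$teeth$loss_distal, 0)

  expect_error(generate_scene(200, seed = 1), "layout error")
  expect_error(generate_scene(10, seed = 1, image_width = 300),
               "layout error")
})

test_that("teeth stay in frame and do not overlap", {
  scene <- generate_scene(14, loss = "uniform", loss_range = c(0, 90), seed = 3)
  ann <- oracle_annotations(scene)
  for (p in ann$teeth$points) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= scene$image_width))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= scene$image_height))
  }
  for (i in 1:(nrow(ann$teeth) - 1)) {
    inter <- poly_iou(ann$teeth$points[[i]], ann$teeth$points[[i + 1]])
    expect_lt(inter, 0.01)
  }
})

test_that("rendering is deterministic and piecewise constant without noise", {
  scene <- generate_scene(3, loss = "fixed", loss_value = 40, seed = 5,
                          noise_level = 0, blur_sigma = 0)
  img1 <- render_scene(scene)
  img2 <- render_scene(scene)
  expect_identical(img1, img2)
  expect_identical(dim(img1), c(scene$image_height, scene$image_width))
  expect_lte(length(unique(as.vector(img1))), 4L)  # bg, bone, tooth, pocket

  noisy <- generate_scene(3, loss = "fixed", loss_value = 40, seed = 5,
                          noise_level = 3, blur_sigma = 0.8)
  expect_identical(render_scene(noisy), render_scene(noisy))
  expect_gt(length(unique(as.vector(render_scene(noisy)))), 4L)
})

test_that("crest placement inverts the bone-loss formula", {
  # 33.33% loss on a 14 mm root (12 mm beyond the biologic width) puts the
  # crest 2 mm + 4 mm below the CEJ
  scene <- generate_scene(2, loss = "fixed", loss_value = 100 / 3, seed = 2)
  scene$teeth$root_len_px <- 140
  scene$teeth$angulation_deg <- 0
  ann <- oracle_annotations(scene)
  lms <- locate_landmarks(ann$teeth, ann$regions)
  sites <- measure_sites(lms, ann$teeth, scene$mm_per_pixel)
  expect_equal(sites$cej_to_apex_mm, rep(14, 4), tolerance = 1e-9)
  expect_equal(sites$cej_to_crest_mm, rep(6, 4), tolerance = 1e-9)
})

test_that("oracle annotations carry exact per-side geometry", {
  scene <- generate_scene(1, loss = "fixed", loss_value = 50, seed = 9)
  ann <- oracle_annotations(scene)
  expect_identical(nrow(ann$teeth), 1L)
  expect_identical(nrow(ann$regions), 2L)
  # region axial extent equals the gap implied by the true loss
  sites <- measure_sites(locate_landmarks(ann$teeth, ann$regions),
                         ann$teeth, scene$mm_per_pixel)
  root_mm <- scene$teeth$root_len_px * scene$mm_per_pixel
  expect_equal(sites$cej_to_crest_mm, rep(2 + 0.5 * (root_mm - 2), 2),
               tolerance = 1e-9)
})

test_that("oracle annotations survive a LabelMe round trip", {
  scene <- generate_scene(4, loss = "uniform", loss_range = c(10, 60), seed = 12)
  f <- tempfile(fileext = ".json")
  write_scene_labelme(scene, f)
  back <- read_labelme(f)
  expect_identical(nrow(back), 4L * 3L)  # one tooth + two regions each
  expect_identical(sum(back$label == "cej_bone_region"), 8L)
  ann <- oracle_annotations(scene)
  orig <- ann$teeth$points[[1]]
  got <- back$points[[which(back$label == paste0("tooth_", ann$teeth$tooth_id[1]))]]
  expect_equal(got, orig, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("perturbation is the identity at zero and drops everything at one", {
  scene <- generate_scene(5, loss = "uniform", loss_range = c(0, 90), seed = 4)
  ann <- oracle_annotations(scene)
  expect_identical(perturb_annotations(ann$teeth, 0, 0, seed = 1), ann$teeth)
  dropped <- perturb_annotations(ann$teeth, 0, 1, seed = 1)
  expect_identical(nrow(dropped), 0L)
  # everything dropped -> zero sensitivity downstream
  m <- match_detections(dropped, ann$teeth)
  expect_identical(m$unmatched_gt, seq_len(5L))

  j1 <- perturb_annotations(ann$teeth, 2, 0, seed = 42)
  j2 <- perturb_annotations(ann$teeth, 2, 0, seed = 42)
  expect_identical(j1, j2)
  expect_false(identical(j1$points[[1]], ann$teeth$points[[1]]))
})

test_that("moderate jitter keeps IoU with the original polygons high", {
  scene <- generate_scene(6, loss = "uniform", loss_range = c(0, 90), seed = 6)
  ann <- oracle_annotations(scene)
  set.seed(99)
  ious <- replicate(200, {
    k <- sample(6, 1)
    jit <- perturb_annotations(ann$teeth[k, ], jitter_px = 2, seed = sample.int(1e6, 1))
    poly_iou(jit$points[[1]], ann$teeth$points[[k]])
  })
  expect_gt(mean(ious > 0.8), 0.95)
})
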