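# Raster, LabelMe, YOLO and report IO.

test_that("read_image handles 8-bit, 16-bit and color rasters", {
  f <- tempfile(fileext = ".png")
  write_image(matrix(255L, 2, 2), f)
  img <- read_image(f)
  expect_identical(dim(img), c(2L, 2L))
  expect_true(all(img == 255L))

  # 16-bit TIFF against a direct linear-rescale oracle
  raw16 <- matrix(c(0, 16384, 32768, 65535) / 65535, 2, 2)
  ft <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(raw16, ft, bits.per.sample = 16L)
  got <- read_image(ft)
  expect_identical(got, matrix(as.integer(round(raw16 * 255)), 2, 2),
                   ignore_attr = TRUE)
  expect_equal(max(got), 255L)

  # color PNG collapses by luminance weights
  arr <- array(0, c(2, 2, 3)); arr[, , 1] <- 1  # pure red
  fc <- tempfile(fileext = ".png")
  png::writePNG(arr, fc)
  expect_true(all(read_image(fc) == round(0.299 * 255)))
})

test_that("read_image rejects corrupt or unknown files", {
  f <- tempfile(fileext = ".png")
  writeLines("not a png", f)
  expect_error(read_image(f), "cannot read image")
  expect_error(read_image(tempfile(fileext = ".png")), "does not exist")
  fx <- tempfile(fileext = ".bmp"); file.create(fx)
  expect_error(read_image(fx), "unsupported image format")
})

test_that("read_image output stays within [0, 255] for random inputs", {
  set.seed(11)
  for (k in 1:5) {
    f <- tempfile(fileext = ".png")
    png::writePNG(matrix(runif(64), 8, 8), f)
    img <- read_image(f)
    expect_true(all(img >= 0 & img <= 255))
  }
})

test_that("read_labelme parses polygons, skips other shapes, checks schema", {
  f <- write_labelme_fixture(tempfile(fileext = ".json"),
    list(shape_entry("tooth", square_poly(10, 10, 10))))
  ann <- read_labelme(f)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$label, "tooth")
  expect_equal(ann$points[[1]][2, ], c(x = 20, y = 10))

  f2 <- write_labelme_fixture(tempfile(fileext = ".json"),
    list(shape_entry("box", square_poly(0, 0, 5), type = "rectangle"),
         shape_entry("tooth", square_poly(10, 10, 10))))
  expect_warning(ann2 <- read_labelme(f2), "non-polygon")
  expect_identical(nrow(ann2), 1L)

  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(shapes = list(), imageWidth = 100), bad,
                       auto_unbox = TRUE)
  expect_error(read_labelme(bad), "imageWidth/imageHeight")
})

test_that("labelme_to_yolo normalizes and errors on unmapped labels", {
  ann <- annotation_tbl("tooth", list(square_poly(10, 10, 10)), 100, 100)
  rec <- labelme_to_yolo(ann, c(tooth = 0L))
  expect_identical(rec$class_index, 0L)
  expect_equal(rec$coords[[1]], c(0.1, 0.1, 0.2, 0.1, 0.2, 0.2, 0.1, 0.2))

  full <- annotation_tbl("tooth", list(rect_poly(0, 0, 100, 100)), 100, 100)
  expect_true(all(labelme_to_yolo(full, c(tooth = 0L))$coords[[1]] %in% c(0, 1)))

  ann$label <- "noise"
  expect_error(labelme_to_yolo(ann, c(tooth = 0L)), "noise")
})

test_that("yolo_to_polygons validates and inverts the conversion", {
  ann <- annotation_tbl("tooth", list(square_poly(10, 10, 10)), 100, 100)
  rec <- labelme_to_yolo(ann, c(tooth = 0L))
  back <- yolo_to_polygons(rec, 100, 100, c("0" = "tooth"))
  expect_equal(back$points[[1]], ann$points[[1]], ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(back$label, "tooth")

  empty <- tibble::tibble(class_index = integer(), coords = list())
  expect_identical(nrow(yolo_to_polygons(empty, 100, 100)), 0L)

  bad <- tibble::tibble(class_index = 0L, coords = list(c(0.1, 0.1, 1.2, 0.1, 0.5, 0.5)))
  expect_error(yolo_to_polygons(bad, 100, 100), "outside \\[0, 1\\]")
})

test_that("LabelMe -> YOLO file -> LabelMe round trip stays within 0.5 px", {
  set.seed(42)
  w <- 1800; h <- 900
  polys <- replicate(50, random_convex_poly(w, h), simplify = FALSE)
  ann <- annotation_tbl(rep("tooth", 50), polys, w, h)
  f <- tempfile(fileext = ".txt")
  write_yolo(labelme_to_yolo(ann, c(tooth = 0L)), f)
  back <- yolo_to_polygons(read_yolo(f), w, h, c("0" = "tooth"))
  err <- max(purrr::map2_dbl(back$points, ann$points,
                             ~ max(abs(.x - .y))))
  expect_lt(err, 0.5)
})

test_that("reports round-trip through CSV and JSON", {
  res <- tibble::tibble(
    tooth_id = c("31", "32", "41"), side = c("mesial", "distal", "mesial"),
    cej_to_crest_mm = c(2, 4.5, 6), cej_to_apex_mm = c(12, 12, 14),
    percent_bone_loss = c(0, 25, 33.3333), bone_support_percent = c(100, 75, 66.6667),
    abnormal_flag = c(FALSE, TRUE, TRUE), prognosis = c("Good", "Fair", "Fair"),
    basis = "radiographic_only")
  fc <- tempfile(fileext = ".csv")
  write_report(res, fc, "csv")
  expect_identical(length(readLines(fc)), 4L)  # header + 3 rows
  back <- read_report(fc, "csv")
  expect_equal(back$percent_bone_loss, round(res$percent_bone_loss, 2),
               tolerance = 1e-4)
  expect_identical(back$tooth_id, as.numeric(res$tooth_id))

  fj <- tempfile(fileext = ".json")
  write_report(res, fj, "json")
  backj <- read_report(fj, "json")
  expect_identical(backj$prognosis, res$prognosis)
  expect_equal(backj$cej_to_crest_mm, res$cej_to_crest_mm, tolerance = 1e-4)

  f0 <- tempfile(fileext = ".csv")
  write_report(res[0, ], f0, "csv")
  expect_identical(length(readLines(f0)), 1L)
})
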