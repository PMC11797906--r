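# Raster, LabelMe JSON, YOLO polygon-label and report IO.
#
# Images are integer matrices in [0, 255], indexed [row = y + 1, col = x + 1];
# polygon vertices are 0-based pixel-center coordinates, origin top-left.

LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Read a grayscale 8-bit raster image
#'
#' Reads PNG, TIFF or JPEG. Color images are converted to gray by the
#' standard luminance weights (0.299, 0.587, 0.114); higher bit depths are
#' rescaled linearly so full scale maps to 255.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return An integer matrix (`height` x `width`) with values in `[0, 255]`
#'   and attribute `source_path`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_image(matrix(255L, 2, 2), f)
#' img <- read_image(f)
#' dim(img)
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("image file does not exist: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  img <- gray_from_array(arr)
  attr(img, "source_path") <- path
  img
}

# Collapse a readPNG/readTIFF/readJPEG array (values in [0,1]) to an
# integer [0,255] matrix.
gray_from_array <- function(arr) {
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    if (nch >= 3L) {
      g <- arr[, , 1L] * LUMA_WEIGHTS[1L] + arr[, , 2L] * LUMA_WEIGHTS[2L] +
        arr[, , 3L] * LUMA_WEIGHTS[3L]
    } else {
      g <- arr[, , 1L]
    }
  } else {
    g <- arr
  }
  m <- round(pmin(pmax(g, 0), 1) * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write an image matrix as PNG
#'
#' @param image Integer matrix in `[0, 255]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 255) / 255, target = path)
  invisible(path)
}

new_annotation_tbl <- function(label = character(), points = list(),
                               image_width = numeric(),
                               image_height = numeric()) {
  tibble::tibble(label = label, points = points,
                 image_width = image_width, image_height = image_height)
}

#' Read LabelMe polygon annotations
#'
#' Parses a LabelMe-dialect JSON file. Only shapes of type `"polygon"` are
#' kept; other shape types are skipped with a warning. Each polygon is
#' cleaned (duplicate consecutive vertices dropped) and must be simple.
#'
#' @param path Path to a LabelMe `.json` file.
#' @return A tibble with one row per polygon: `label`, `points` (list of
#'   n x 2 matrices), `image_width`, `image_height`.
#' @export
read_labelme <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
    error = function(e) stop(sprintf("cannot parse LabelMe JSON '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (is.null(doc$imageWidth) || is.null(doc$imageHeight)) {
    stop(sprintf("LabelMe file '%s' lacks imageWidth/imageHeight", path),
         call. = FALSE)
  }
  w <- as.numeric(doc$imageWidth)
  h <- as.numeric(doc$imageHeight)
  shapes <- doc$shapes %||% list()
  keep <- vapply(shapes, function(s) identical(s$shape_type, "polygon"), logical(1))
  if (any(!keep)) {
    warning(sprintf("%s: skipped %d non-polygon shape(s)", path, sum(!keep)),
            call. = FALSE)
  }
  shapes <- shapes[keep]
  polys <- purrr::map(shapes, function(s) {
    pts <- do.call(rbind, purrr::map(s$points, ~ as.numeric(unlist(.x))))
    validate_polygon(pts, context = sprintf("shape '%s' in %s", s$label, path))
  })
  new_annotation_tbl(
    label = purrr::map_chr(shapes, ~ as.character(.x$label)),
    points = polys,
    image_width = rep(w, length(polys)),
    image_height = rep(h, length(polys))
  )
}

#' Write polygon annotations as LabelMe JSON
#'
#' @param annotations Annotation tibble as returned by [read_labelme()].
#' @param path Output `.json` path.
#' @param image_path Value for the LabelMe `imagePath` field.
#' @return `path`, invisibly.
#' @export
write_labelme <- function(annotations, path, image_path = "") {
  stopifnot(nrow(annotations) == 0L || all(c("label", "points") %in% names(annotations)))
  w <- if (nrow(annotations)) annotations$image_width[[1L]] else 0
  h <- if (nrow(annotations)) annotations$image_height[[1L]] else 0
  shapes <- purrr::pmap(annotations, function(label, points, ...) {
    pts <- lapply(seq_len(nrow(points)), function(i) unname(points[i, ]))
    list(label = label, points = pts,
         group_id = NULL, shape_type = "polygon", flags = c())
  })
  doc <- list(version = "5.0.0", flags = c(), shapes = shapes,
              imagePath = image_path, imageData = NULL,
              imageHeight = h, imageWidth = w)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Convert LabelMe polygons to YOLO polygon records
#'
#' Normalizes vertex coordinates by the image width/height, preserving
#' vertex order, in the one-object-per-line dialect the LabelMe-to-YOLO
#' converters emit.
#'
#' @param annotations Annotation tibble (see [read_labelme()]).
#' @param class_map Named integer vector mapping label -> class index.
#' @return A tibble with `class_index` and `coords` (list of flat numeric
#'   vectors `x1, y1, x2, y2, ...` in `[0, 1]`).
#' @export
labelme_to_yolo <- function(annotations, class_map) {
  missing_labels <- setdiff(unique(annotations$label), names(class_map))
  if (length(missing_labels)) {
    stop(sprintf("label(s) not in class map: %s",
                 paste(missing_labels, collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    class_index = as.integer(class_map[annotations$label]),
    coords = purrr::pmap(annotations, function(points, image_width, image_height, ...) {
      as.numeric(t(cbind(points[, 1L] / image_width, points[, 2L] / image_height)))
    })
  )
}

#' Convert YOLO polygon records back to pixel polygons
#'
#' Inverse of [labelme_to_yolo()]; round-trips reproduce pixel vertices to
#' within the serialization quantization (0.5 px at 6 decimals).
#'
#' @param records Tibble with `class_index` and `coords` columns.
#' @param image_width,image_height Raster dimensions in pixels.
#' @param class_map_inverse Named character vector or function mapping class
#'   index -> label; by default indices become `"class_<i>"`.
#' @return An annotation tibble (see [read_labelme()]).
#' @export
yolo_to_polygons <- function(records, image_width, image_height,
                             class_map_inverse = NULL) {
  bad <- purrr::map_lgl(records$coords, ~ any(.x < 0 | .x > 1))
  if (any(bad)) {
    stop("YOLO coordinates outside [0, 1] in record(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  to_label <- function(i) {
    if (is.null(class_map_inverse)) return(sprintf("class_%d", i))
    if (is.function(class_map_inverse)) return(class_map_inverse(i))
    unname(class_map_inverse[as.character(i)])
  }
  new_annotation_tbl(
    label = purrr::map_chr(records$class_index, to_label),
    points = purrr::map(records$coords, function(cc) {
      m <- matrix(cc, ncol = 2L, byrow = TRUE)
      cbind(x = m[, 1L] * image_width, y = m[, 2L] * image_height)
    }),
    image_width = rep(as.numeric(image_width), nrow(records)),
    image_height = rep(as.numeric(image_height), nrow(records))
  )
}

#' Write and read YOLO polygon label files
#'
#' One object per line: `class x1 y1 x2 y2 ...`, normalized floats with six
#' decimals.
#'
#' @param records Tibble with `class_index` and `coords`.
#' @param path `.txt` label file path.
#' @return `write_yolo()` returns `path` invisibly; `read_yolo()` the records
#'   tibble.
#' @export
write_yolo <- function(records, path) {
  lines <- purrr::pmap_chr(records, function(class_index, coords, ...) {
    paste(class_index, paste(sprintf("%.6f", coords), collapse = " "))
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo
#' @export
read_yolo <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- purrr::map(lines, function(ln) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    ncoord <- length(v) - 1L
    if (ncoord < 6L || ncoord %% 2L != 0L) {
      stop(sprintf("malformed YOLO polygon line in '%s': %s", path, ln),
           call. = FALSE)
    }
    list(class_index = as.integer(v[1L]), coords = v[-1L])
  })
  tibble::tibble(
    class_index = purrr::map_int(parsed, "class_index"),
    coords = purrr::map(parsed, "coords")
  )
}

#' Write and re-read per-tooth bone-loss reports
#'
#' One row per measured site with per-tooth aggregates: tooth id, side, CEJ
#' to crest (A, mm), CEJ to apex (C, mm), percent bone loss, bone support,
#' abnormality flag and prognosis. Percent columns are rounded to 2 decimals
#' in the written file.
#'
#' @param results Site-level results tibble (see [measure_bone_loss()] and
#'   [classify_dentition()]).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   tibble re-parsed from disk.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- tibble::as_tibble(results)
  num_cols <- intersect(c("percent_bone_loss", "bone_support_percent"), names(out))
  for (cl in num_cols) out[[cl]] <- round(out[[cl]], 2)
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
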