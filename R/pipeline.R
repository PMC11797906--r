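# End-to-end analysis: enhance -> detect (external labels or oracle) ->
# landmark geometry -> bone loss -> prognosis -> report.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with its default. The
#' calibration has no general default — panoramic magnification is
#' device-dependent — and must be supplied for real images; synthetic scenes
#' carry their own (0.1 mm/px).
#'
#' @param mm_per_pixel Calibration, mm per pixel (required for analysis).
#' @param sharpen_amount,equalize,smooth Enhancement-stage settings (see
#'   [enhance()]); `apply_enhancement` gates the whole stage.
#' @param apply_enhancement Run the enhancement chain before analysis?
#'   Enhancement feeds annotation and detection; landmark geometry itself
#'   only uses the polygons, so the default is `FALSE`.
#' @param biologic_width_mm,threshold_mm Bone-loss constants, mm.
#' @param min_overlap_fraction Region-to-tooth assignment cutoff.
#' @param cell_size Evaluation-grid cell edge, px.
#' @param iou_threshold Detection-matching IoU threshold.
#' @return A named list of class `"periobone_config"`.
#' @export
periobone_config <- function(mm_per_pixel = NULL,
                             sharpen_amount = 1, equalize = TRUE, smooth = TRUE,
                             apply_enhancement = FALSE,
                             biologic_width_mm = 2, threshold_mm = 2,
                             min_overlap_fraction = 0.05,
                             cell_size = 64, iou_threshold = 0.5) {
  cfg <- list(
    mm_per_pixel = mm_per_pixel,
    sharpen_amount = sharpen_amount, equalize = equalize, smooth = smooth,
    apply_enhancement = apply_enhancement,
    biologic_width_mm = biologic_width_mm, threshold_mm = threshold_mm,
    min_overlap_fraction = min_overlap_fraction,
    cell_size = cell_size, iou_threshold = iou_threshold
  )
  if (!is.null(cfg$mm_per_pixel) && !is.na(cfg$mm_per_pixel) &&
      cfg$mm_per_pixel <= 0) {
    stop("config error: mm_per_pixel must be positive", call. = FALSE)
  }
  structure(cfg, class = "periobone_config")
}

#' @export
print.periobone_config <- function(x, ...) {
  cat("periobone configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "(unset)" else format(x[[nm]])))
  }
  invisible(x)
}

#' Read a YAML configuration file
#'
#' Keys mirror the arguments of [periobone_config()]; dotted config-file
#' keys (`calibration.mm_per_pixel`, `boneloss.biologic_width_mm`,
#' `boneloss.threshold_mm`, `geometry.min_overlap_fraction`) are accepted as
#' nested sections.
#'
#' @param path YAML file path.
#' @return A `"periobone_config"`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  flat <- list(
    mm_per_pixel = y$calibration$mm_per_pixel %||% y$mm_per_pixel,
    biologic_width_mm = y$boneloss$biologic_width_mm %||% y$biologic_width_mm,
    threshold_mm = y$boneloss$threshold_mm %||% y$threshold_mm,
    min_overlap_fraction = y$geometry$min_overlap_fraction %||%
      y$min_overlap_fraction
  )
  flat <- flat[!vapply(flat, is.null, logical(1))]
  extra <- y[intersect(names(y), setdiff(names(formals(periobone_config)),
                                         names(flat)))]
  do.call(periobone_config, c(flat, extra))
}

# Split a LabelMe annotation tibble into detections + regions on the
# label convention tooth[_<FDI>] / cej_bone_region.
parse_annotation_labels <- function(annotations) {
  is_tooth <- grepl("^tooth", annotations$label)
  is_region <- annotations$label == "cej_bone_region"
  unknown <- !is_tooth & !is_region
  if (any(unknown)) {
    warning(sprintf("ignoring %d annotation(s) with unrecognized label(s): %s",
                    sum(unknown),
                    paste(unique(annotations$label[unknown]), collapse = ", ")),
            call. = FALSE)
  }
  teeth_tbl <- annotations[is_tooth, , drop = FALSE]
  ids <- sub("^tooth[_-]?", "", teeth_tbl$label)
  ids[!grepl("^[1-4][1-8]$", ids)] <- NA
  ids[is.na(ids)] <- paste0("unassigned_", seq_len(sum(is.na(ids))))
  list(
    teeth = tibble::tibble(tooth_id = ids, points = teeth_tbl$points,
                           confidence = 1),
    regions = tibble::tibble(points = annotations$points[is_region],
                             confidence = 1)
  )
}

#' Analyze one radiograph end to end
#'
#' Reads the image and its polygon annotations (any detector's output in
#' LabelMe JSON; teeth labelled `tooth_<FDI>`, CEJ-bone regions
#' `cej_bone_region`), optionally applies the enhancement chain, extracts
#' landmarks, computes per-site and per-tooth bone loss, classifies
#' prognosis, and writes the report. With no teeth detected an empty report
#' is written with a warning.
#'
#' @param image_path Radiograph (PNG/TIFF/JPEG); `NULL` to analyze
#'   annotations alone.
#' @param annotations_path LabelMe JSON with the detections.
#' @param out_path Report destination.
#' @param config A [periobone_config()] with `mm_per_pixel` set.
#' @param clinical Optional per-tooth clinical tibble (see
#'   [classify_dentition()]).
#' @param format Report format, `"csv"` or `"json"`.
#' @return Invisibly, a list with `sites`, `teeth` (classified per-tooth
#'   results), `greatest` (worst tooth) and `report_path`.
#' @export
analyze <- function(image_path = NULL, annotations_path, out_path,
                    config = periobone_config(), clinical = NULL,
                    format = c("csv", "json")) {
  format <- match.arg(format)
  if (is.null(config$mm_per_pixel)) {
    stop("config error: mm_per_pixel calibration is required", call. = FALSE)
  }
  if (!is.null(image_path)) {
    img <- read_image(image_path)
    if (isTRUE(config$apply_enhancement)) {
      img <- enhance(img, sharpen_amount = config$sharpen_amount,
                     equalize = config$equalize, smooth = config$smooth)
    }
  }
  ann <- read_labelme(annotations_path)
  det <- parse_annotation_labels(ann)
  if (nrow(det$teeth) == 0L) {
    warning("no teeth detected; writing empty report", call. = FALSE)
    empty <- tibble::tibble(tooth_id = character(), side = character(),
                            cej_to_crest_mm = numeric(),
                            cej_to_apex_mm = numeric(),
                            percent_bone_loss = numeric(),
                            bone_support_percent = numeric(),
                            abnormal_flag = logical(),
                            prognosis = character(), basis = character())
    write_report(empty, out_path, format = format)
    return(invisible(list(sites = empty, teeth = empty, greatest = NULL,
                          report_path = out_path)))
  }
  landmarks <- locate_landmarks(det$teeth, det$regions,
                                min_overlap = config$min_overlap_fraction)
  sites <- measure_sites(landmarks, det$teeth, config$mm_per_pixel) |>
    measure_bone_loss(biologic_width_mm = config$biologic_width_mm,
                      threshold_mm = config$threshold_mm)
  teeth <- aggregate_teeth(sites) |>
    classify_dentition(clinical = clinical)
  site_report <- dplyr::left_join(
    sites,
    dplyr::select(teeth, "tooth_id", "bone_support_percent",
                  "prognosis", "basis"),
    by = "tooth_id"
  )
  write_report(site_report, out_path, format = format)
  invisible(list(sites = sites, teeth = teeth,
                 greatest = greatest_loss(teeth), report_path = out_path))
}

#' Convert a directory of LabelMe files to YOLO labels
#'
#' Writes one `.txt` label file per input JSON plus a `classes.txt` listing
#' the class order. Per-file failures are collected and reported; the
#' successful conversions are still written.
#'
#' @param labelme_dir Directory of LabelMe `.json` files.
#' @param out_dir Output directory (created if needed).
#' @param class_map Named integer vector label -> class index; `NULL` infers
#'   one from the labels seen (alphabetical, 0-based).
#' @return Invisibly, a list with `converted` (paths) and `failed` (named
#'   character vector of error messages).
#' @export
convert_labelme_dir <- function(labelme_dir, out_dir, class_map = NULL) {
  files <- list.files(labelme_dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) {
    warning(sprintf("no LabelMe JSON files found in '%s'", labelme_dir),
            call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(class_map) && length(files)) {
    labels <- sort(unique(unlist(lapply(files, function(f) {
      tryCatch(read_labelme(f)$label, error = function(e) character())
    }))))
    class_map <- stats::setNames(seq_along(labels) - 1L, labels)
  }
  converted <- character()
  failed <- character()
  for (f in files) {
    res <- tryCatch({
      ann <- read_labelme(f)
      rec <- labelme_to_yolo(ann, class_map)
      out <- file.path(out_dir, paste0(tools::file_path_sans_ext(basename(f)),
                                       ".txt"))
      write_yolo(rec, out)
      out
    }, error = function(e) structure(conditionMessage(e), class = "fail"))
    if (inherits(res, "fail")) failed[f] <- unclass(res) else
      converted <- c(converted, res)
  }
  if (length(class_map)) {
    writeLines(names(sort(class_map)), file.path(out_dir, "classes.txt"))
  }
  if (length(failed)) {
    warning(sprintf("%d file(s) failed to convert", length(failed)),
            call. = FALSE)
  }
  invisible(list(converted = converted, failed = failed))
}
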