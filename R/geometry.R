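# Per-tooth landmark geometry: tooth axis from area moments, CEJ/crest/apex
# extraction from CEJ-bone-region polygons, and millimeter distances along
# the axis.
#
# The three landmarks follow the standard radiographic construction: A is
# the cemento-enamel junction (CEJ), B the alveolar bone crest, C the root
# apex; distances A->B (gap width) and A->C (root length from the CEJ) are
# measured as projections onto the tooth's long axis.

#' Fit a tooth's long axis from its polygon
#'
#' The axis is the principal axis of the polygon's area moments, anchored at
#' the area centroid. Its direction (crown toward apex) cannot be recovered
#' from moments alone, so the sign is set by `orientation_hint` (any vector
#' with positive dot product wins); without a hint, the direction with
#' non-negative y (apex inferior, the mandibular convention) is chosen, with
#' ties (horizontal axes) broken toward positive x. Perfectly isotropic
#' polygons (squares, circles) fall back to the vertical axis `(0, 1)`.
#'
#' @param points Tooth polygon, n x 2 matrix (x, y in pixels).
#' @param orientation_hint Optional length-2 vector indicating the crown ->
#'   apex direction (e.g. `c(0, -1)` for maxillary teeth).
#' @return A list with `origin` (centroid, length-2) and `direction`
#'   (unit length-2), of class `"tooth_axis"`.
#' @export
fit_tooth_axis <- function(points, orientation_hint = NULL) {
  p <- validate_polygon(points, context = "tooth polygon")
  if (polygon_area(p) <= 0) stop("degenerate tooth polygon (zero area)", call. = FALSE)
  ctr <- polygon_centroid(p)
  cv <- polygon_covariance(p)
  eg <- eigen(cv, symmetric = TRUE)
  if ((eg$values[1L] - eg$values[2L]) < 1e-9 * max(eg$values[1L], 1e-12)) {
    d <- c(0, 1)  # isotropic: documented vertical fallback
  } else {
    d <- eg$vectors[, 1L]
  }
  d <- d / sqrt(sum(d^2))
  if (!is.null(orientation_hint)) {
    s <- sum(d * orientation_hint)
    if (s < 0) d <- -d
  } else if (d[2L] < 0 || (d[2L] == 0 && d[1L] < 0)) {
    d <- -d
  }
  structure(list(origin = unname(ctr), direction = unname(d)),
            class = "tooth_axis")
}

# Scalar axial coordinate (px) of points along an axis.
axial_coord <- function(points, axis) {
  pts <- matrix(as.numeric(points), ncol = 2L)
  (pts[, 1L] - axis$origin[1L]) * axis$direction[1L] +
    (pts[, 2L] - axis$origin[2L]) * axis$direction[2L]
}

# Signed perpendicular offset, positive toward increasing x for a
# downward-pointing axis (used for the mesial/distal half-plane test).
perp_offset <- function(points, axis) {
  pts <- matrix(as.numeric(points), ncol = 2L)
  u <- c(axis$direction[2L], -axis$direction[1L])
  if (u[1L] < 0) u <- -u
  (pts[, 1L] - axis$origin[1L]) * u[1L] + (pts[, 2L] - axis$origin[2L]) * u[2L]
}

#' Millimeter distance between two points along a tooth axis
#'
#' Absolute projection of `q - p` onto the axis direction, scaled by the
#' calibration. Symmetric and non-negative; perpendicular displacements
#' measure zero.
#'
#' @param p,q Length-2 points (x, y) in pixels.
#' @param axis A `"tooth_axis"` from [fit_tooth_axis()].
#' @param mm_per_pixel Calibration, mm per pixel (> 0).
#' @return Distance in millimeters.
#' @export
axial_distance <- function(p, q, axis, mm_per_pixel) {
  stopifnot(mm_per_pixel > 0)
  abs(axial_coord(rbind(q), axis) - axial_coord(rbind(p), axis)) * mm_per_pixel
}

#' Assign CEJ-bone regions to teeth by overlap fraction
#'
#' Each region goes to the tooth whose polygon covers the greatest fraction
#' of the region's area (overlap fraction of the region, not IoU — the
#' regions are much smaller than teeth). Regions whose best overlap is at or
#' below `min_overlap` stay unassigned (`tooth_id = NA`) with a warning.
#'
#' @param teeth Detections tibble: `tooth_id`, `points` (list of polygons),
#'   `confidence`.
#' @param regions Regions tibble: `points` (list of polygons), `confidence`.
#' @param min_overlap Minimum overlap fraction for assignment (default 0.05).
#' @return `regions` with columns `region_id`, `tooth_id`, `overlap_fraction`.
#' @export
assign_regions_to_teeth <- function(teeth, regions, min_overlap = 0.05) {
  out <- tibble::as_tibble(regions)
  out$region_id <- seq_len(nrow(out))
  if (nrow(out) == 0L) {
    out$tooth_id <- character()
    out$overlap_fraction <- numeric()
    return(out)
  }
  hits <- purrr::map(out$points, function(rp) {
    ra <- polygon_area(rp)
    fr <- vapply(teeth$points, function(tp) poly_intersection_area(rp, tp) / ra,
                 numeric(1))
    if (!length(fr) || max(fr) <= min_overlap) {
      list(tooth_id = NA_character_, frac = if (length(fr)) max(fr) else 0)
    } else {
      list(tooth_id = as.character(teeth$tooth_id[[which.max(fr)]]), frac = max(fr))
    }
  })
  out$tooth_id <- purrr::map_chr(hits, "tooth_id")
  out$overlap_fraction <- purrr::map_dbl(hits, "frac")
  n_orphan <- sum(is.na(out$tooth_id))
  if (n_orphan > 0L) {
    warning(sprintf("%d region(s) overlap no tooth above %.2f and were left unassigned",
                    n_orphan, min_overlap), call. = FALSE)
  }
  out
}

fdi_quadrant <- function(tooth_id) {
  q <- suppressWarnings(as.integer(substr(as.character(tooth_id), 1L, 1L)))
  ifelse(!is.na(q) & q >= 1L & q <= 4L, q, NA_integer_)
}

# Crown -> apex hint from the FDI quadrant: maxillary (1, 2) apices point
# up (-y), mandibular (3, 4) down (+y); unknown -> NULL (vertical default).
fdi_orientation_hint <- function(tooth_id) {
  q <- fdi_quadrant(tooth_id)
  if (is.na(q)) return(NULL)
  if (q <= 2L) c(0, -1) else c(0, 1)
}

# Mesial is toward the arch midline: on a panoramic frame the patient's
# right (quadrants 1, 4) occupies the image left, so mesial is the +x side
# there and the -x side for quadrants 2, 3.
side_from_offset <- function(offset, tooth_id) {
  q <- fdi_quadrant(tooth_id)
  if (is.na(q) || abs(offset) < 1e-9) return("midline")
  toward_positive_x <- q %in% c(1L, 4L)
  if ((offset > 0) == toward_positive_x) "mesial" else "distal"
}

#' Extract CEJ, bone-crest and apex landmarks for one tooth site
#'
#' The CEJ (A) is the region vertex with the smallest axial coordinate (most
#' coronal), the alveolar crest (B) the region vertex with the largest (most
#' apical), and the root apex (C) the tooth-polygon vertex with the largest
#' axial coordinate. The site side (mesial/distal) comes from a half-plane
#' test of the region centroid against the axis, interpreted through the FDI
#' quadrant; without an FDI code the side is `"midline"`.
#'
#' @param tooth_points Tooth polygon (n x 2 matrix).
#' @param region_points CEJ-bone region polygon (n x 2 matrix).
#' @param axis A `"tooth_axis"`; defaults to [fit_tooth_axis()] on the tooth.
#' @param tooth_id FDI code (used for side orientation), or `NA`.
#' @return One-row tibble: `tooth_id`, `side`, `cej`, `crest`, `apex`
#'   (each a list-column holding an (x, y) point).
#' @export
extract_landmarks <- function(tooth_points, region_points, axis = NULL,
                              tooth_id = NA_character_) {
  tp <- validate_polygon(tooth_points, "tooth polygon")
  rp <- validate_polygon(region_points, "CEJ-bone region polygon")
  if (is.null(axis)) {
    axis <- fit_tooth_axis(tp, orientation_hint = fdi_orientation_hint(tooth_id))
  }
  t_reg <- axial_coord(rp, axis)
  t_tooth <- axial_coord(tp, axis)
  cej <- rp[which.min(t_reg), ]
  crest <- rp[which.max(t_reg), ]
  apex <- tp[which.max(t_tooth), ]
  if (max(t_reg) > max(t_tooth) + 1e-6) {
    stop("invalid region: crest apical to the root apex", call. = FALSE)
  }
  side <- side_from_offset(perp_offset(rbind(polygon_centroid(rp)), axis), tooth_id)
  tibble::tibble(
    tooth_id = as.character(tooth_id),
    side = side,
    cej = list(unname(cej)),
    crest = list(unname(crest)),
    apex = list(unname(apex))
  )
}

#' Locate landmarks for every assigned region in a detection set
#'
#' Pipeline convenience: assigns regions to teeth, fits each tooth's axis
#' (oriented by its FDI quadrant) and extracts one landmark set per
#' assigned region.
#'
#' @inheritParams assign_regions_to_teeth
#' @return Landmark tibble (one row per assigned region) with `tooth_id`,
#'   `side`, `cej`, `crest`, `apex`.
#' @export
locate_landmarks <- function(teeth, regions, min_overlap = 0.05) {
  assigned <- assign_regions_to_teeth(teeth, regions, min_overlap = min_overlap)
  assigned <- assigned[!is.na(assigned$tooth_id), , drop = FALSE]
  if (nrow(assigned) == 0L) {
    return(tibble::tibble(tooth_id = character(), side = character(),
                          cej = list(), crest = list(), apex = list()))
  }
  axes <- stats::setNames(
    purrr::map(seq_len(nrow(teeth)), function(i) {
      fit_tooth_axis(teeth$points[[i]],
                     orientation_hint = fdi_orientation_hint(teeth$tooth_id[[i]]))
    }),
    as.character(teeth$tooth_id)
  )
  tooth_pts <- stats::setNames(teeth$points, as.character(teeth$tooth_id))
  purrr::pmap_dfr(assigned, function(points, tooth_id, ...) {
    extract_landmarks(tooth_pts[[tooth_id]], points,
                      axis = axes[[tooth_id]], tooth_id = tooth_id)
  })
}

#' Convert landmark sets to millimeter site measurements
#'
#' Projects the A->B (CEJ to crest) and A->C (CEJ to apex) spans onto each
#' tooth's axis and scales by the calibration.
#'
#' @param landmarks Landmark tibble from [locate_landmarks()].
#' @param teeth Detections tibble the landmarks came from (for axis refit).
#' @param mm_per_pixel Calibration, mm per pixel (> 0).
#' @return Site tibble: `tooth_id`, `side`, `cej_to_crest_mm`,
#'   `cej_to_apex_mm`.
#' @export
measure_sites <- function(landmarks, teeth, mm_per_pixel) {
  stopifnot(mm_per_pixel > 0)
  axes <- stats::setNames(
    purrr::map(seq_len(nrow(teeth)), function(i) {
      fit_tooth_axis(teeth$points[[i]],
                     orientation_hint = fdi_orientation_hint(teeth$tooth_id[[i]]))
    }),
    as.character(teeth$tooth_id)
  )
  purrr::pmap_dfr(landmarks, function(tooth_id, side, cej, crest, apex, ...) {
    ax <- axes[[tooth_id]]
    # snap to nanometer precision: projection float dust must not trip
    # strict threshold comparisons (e.g. a healthy gap of exactly 2 mm)
    tibble::tibble(
      tooth_id = tooth_id,
      side = side,
      cej_to_crest_mm = round(axial_distance(cej, crest, ax, mm_per_pixel), 9),
      cej_to_apex_mm = round(axial_distance(cej, apex, ax, mm_per_pixel), 9)
    )
  })
}
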