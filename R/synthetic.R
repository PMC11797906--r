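# Synthetic panoramic-like scenes with fully known per-tooth geometry and
# bone-loss percentages, plus an oracle "detector" that returns the exact
# polygons.  Teeth are simplified trapezoid-crown / tapered-root shapes on a
# darker bone background: the geometry, not the texture, is what the
# downstream modules consume.  Bone-crest positions are placed by inverting
# the bone-loss formula, so parameter recovery is testable end to end.

FULL_LOWER_ARCH <- c(paste0("4", 8:1), paste0("3", 1:8))

rotate_about <- function(points, center, angle_deg) {
  th <- angle_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(sweep(points, 2L, center) %*% t(r), 2L, center, `+`)
}

#' Generate a synthetic dental scene
#'
#' Lays out `n_teeth` simplified lower-arch teeth left to right with FDI
#' codes, drawing each side's (mesial/distal) true bone-loss percentage from
#' the requested distribution. Reproducible under `seed`.
#'
#' @param n_teeth Number of teeth (1 to 16, a full lower arch).
#' @param loss `"uniform"` (draw per side from `loss_range`) or `"fixed"`
#'   (every side at `loss_value`).
#' @param loss_range Length-2 range of percent bone loss for `"uniform"`
#'   (default `c(0, 90)`).
#' @param loss_value Percent bone loss for `"fixed"` (default 0).
#' @param seed Integer seed.
#' @param mm_per_pixel Synthetic calibration (default 0.1 mm/px).
#' @param image_width,image_height Frame size in pixels; `NULL` sizes the
#'   frame to fit the teeth. An explicit frame too small to hold the arch is
#'   a layout error.
#' @param noise_level Gaussian pixel-noise standard deviation for rendering
#'   (default 2).
#' @param blur_sigma Rendering blur, approximated by repeated 3x3 Gaussian
#'   passes (default 0.5).
#' @return A `"periobone_scene"` object: frame size, calibration, rendering
#'   parameters and a `teeth` tibble holding per-tooth shape parameters and
#'   per-side true loss.
#' @export
generate_scene <- function(n_teeth = 14, loss = c("uniform", "fixed"),
                           loss_range = c(0, 90), loss_value = 0, seed = 1L,
                           mm_per_pixel = 0.1,
                           image_width = NULL, image_height = NULL,
                           noise_level = 2, blur_sigma = 0.5) {
  loss <- match.arg(loss)
  stopifnot(n_teeth >= 1)
  if (n_teeth > length(FULL_LOWER_ARCH)) {
    stop(sprintf("layout error: %d teeth exceed a full arch of %d",
                 n_teeth, length(FULL_LOWER_ARCH)), call. = FALSE)
  }
  drop_each_side <- (length(FULL_LOWER_ARCH) - n_teeth) %/% 2
  ids <- FULL_LOWER_ARCH[seq(drop_each_side + 1L,
                             drop_each_side + n_teeth)]
  pitch <- 90
  margin <- 60
  need_w <- n_teeth * pitch + 2 * margin
  need_h <- 420
  if (is.null(image_width)) image_width <- need_w
  if (is.null(image_height)) image_height <- need_h
  if (image_width < need_w || image_height < need_h) {
    stop(sprintf("layout error: %d teeth need a %d x %d frame, got %d x %d",
                 n_teeth, need_w, need_h, image_width, image_height),
         call. = FALSE)
  }
  teeth <- withr::with_seed(seed, {
    draw_loss <- function(k) {
      switch(loss,
        uniform = stats::runif(k, loss_range[1L], loss_range[2L]),
        fixed = rep(loss_value, k))
    }
    tibble::tibble(
      tooth_id = ids,
      cx = margin + pitch * (seq_len(n_teeth) - 0.5),
      y_top = 110 + stats::runif(n_teeth, -8, 8),
      crown_h_px = 58 + stats::runif(n_teeth, -6, 6),
      root_len_px = 120 + stats::runif(n_teeth, -12, 12),
      crown_half_w_px = 27 + stats::runif(n_teeth, -3, 3),
      root_half_w_px = 0.72 * crown_half_w_px,
      angulation_deg = stats::runif(n_teeth, -8, 8),
      loss_mesial = draw_loss(n_teeth),
      loss_distal = draw_loss(n_teeth)
    )
  })
  structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    mm_per_pixel = mm_per_pixel,
    biologic_width_mm = 2,
    noise_level = noise_level,
    blur_sigma = blur_sigma,
    seed = as.integer(seed),
    teeth = teeth
  ), class = "periobone_scene")
}

#' @export
print.periobone_scene <- function(x, ...) {
  cat(sprintf("Synthetic dental scene: %d teeth, %d x %d px, %.3g mm/px, seed %d\n",
              nrow(x$teeth), x$image_width, x$image_height, x$mm_per_pixel,
              x$seed))
  invisible(x)
}

# Unrotated tooth outline: trapezoid crown over a root tapering to a single
# apex vertex on the axis.
tooth_outline <- function(tt) {
  cbind(
    x = c(tt$cx - tt$crown_half_w_px, tt$cx + tt$crown_half_w_px,
          tt$cx + tt$root_half_w_px, tt$cx, tt$cx - tt$root_half_w_px),
    y = c(tt$y_top, tt$y_top, tt$y_top + tt$crown_h_px,
          tt$y_top + tt$crown_h_px + tt$root_len_px,
          tt$y_top + tt$crown_h_px)
  )
}

# CEJ-to-crest distance in px implied by a true loss percentage: the
# inverse of the bone-loss formula.
gap_px_from_loss <- function(loss_percent, root_len_px, mm_per_pixel,
                             biologic_width_mm = 2) {
  root_mm <- root_len_px * mm_per_pixel
  gap_mm <- biologic_width_mm + loss_percent / 100 * (root_mm - biologic_width_mm)
  gap_mm / mm_per_pixel
}

# Thin quadrilateral along one root side spanning axially from the CEJ to
# the crest implied by the side's true loss.  side_sign +1 = tooth's +x
# side before rotation.
region_outline <- function(tt, side_sign, loss_percent, mm_per_pixel,
                           biologic_width_mm = 2) {
  a_px <- gap_px_from_loss(loss_percent, tt$root_len_px, mm_per_pixel,
                           biologic_width_mm)
  y_cej <- tt$y_top + tt$crown_h_px
  x_in <- tt$cx + side_sign * 0.30 * tt$root_half_w_px
  x_out <- tt$cx + side_sign * 0.90 * tt$root_half_w_px
  cbind(x = c(x_in, x_out, x_out, x_in),
        y = c(y_cej, y_cej, y_cej + a_px, y_cej + a_px))
}

scene_polys <- function(scene) {
  purrr::pmap(scene$teeth, function(...) {
    tt <- list(...)
    center <- c(tt$cx, tt$y_top + tt$crown_h_px)
    quadrant <- fdi_quadrant(tt$tooth_id)
    mesial_sign <- if (quadrant == 4L) +1 else -1
    rot <- function(p) rotate_about(p, center, tt$angulation_deg)
    list(
      tooth_id = tt$tooth_id,
      tooth = rot(tooth_outline(tt)),
      mesial = rot(region_outline(tt, mesial_sign, tt$loss_mesial,
                                  scene$mm_per_pixel, scene$biologic_width_mm)),
      distal = rot(region_outline(tt, -mesial_sign, tt$loss_distal,
                                  scene$mm_per_pixel, scene$biologic_width_mm))
    )
  })
}

#' True per-side bone loss behind a scene
#'
#' @param scene A `"periobone_scene"`.
#' @return Tibble: `tooth_id`, `side`, `true_percent`.
#' @export
scene_truth <- function(scene) {
  scene$teeth |>
    dplyr::select("tooth_id", mesial = "loss_mesial", distal = "loss_distal") |>
    tidyr::pivot_longer(c("mesial", "distal"), names_to = "side",
                        values_to = "true_percent")
}

#' Render a scene to a grayscale image
#'
#' Bright teeth on a darker bone band over a dark background; the resorbed
#' CEJ-to-crest pockets are drawn darker so the crest position implied by
#' each side's true loss is visible. Gaussian pixel noise (`noise_level`)
#' and repeated 3x3 Gaussian blur passes (`blur_sigma`) are applied last.
#' Deterministic for a fixed scene (noise uses the scene seed).
#'
#' @param scene A `"periobone_scene"`.
#' @return An integer image matrix (`image_height` x `image_width`).
#' @export
render_scene <- function(scene) {
  w <- scene$image_width; h <- scene$image_height
  img <- matrix(30, h, w)
  bone_top <- stats::median(scene$teeth$y_top + scene$teeth$crown_h_px) +
    scene$biologic_width_mm / scene$mm_per_pixel
  img[(seq_len(h) - 0.5) > bone_top, ] <- 110
  fill_poly <- function(img, poly, value) {
    xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
    cols <- seq(max(1L, floor(xr[1L])), min(w, ceiling(xr[2L]) + 1L))
    rows <- seq(max(1L, floor(yr[1L])), min(h, ceiling(yr[2L]) + 1L))
    if (!length(cols) || !length(rows)) return(img)
    grid <- expand.grid(x = cols - 0.5, y = rows - 0.5)
    inside <- points_in_polygon(as.matrix(grid), poly)
    idx <- cbind(rep(rows, each = length(cols))[inside],
                 rep(cols, times = length(rows))[inside])
    img[idx] <- value
    img
  }
  polys <- scene_polys(scene)
  for (p in polys) img <- fill_poly(img, p$tooth, 200)
  for (p in polys) {
    img <- fill_poly(img, p$mesial, 70)
    img <- fill_poly(img, p$distal, 70)
  }
  if (scene$noise_level > 0) {
    noise <- withr::with_seed(scene$seed + 1L,
                              matrix(stats::rnorm(h * w, 0, scene$noise_level), h, w))
    img <- img + noise
  }
  img <- clip8(img)
  n_passes <- max(0L, round((scene$blur_sigma / 0.85)^2))
  for (k in seq_len(n_passes)) img <- gaussian_smooth(img)
  img
}

#' Oracle detections for a scene
#'
#' Returns the scene's exact analytic polygons at confidence 1: the perfect
#' detector used as ground truth and for end-to-end pipeline tests.
#'
#' @param scene A `"periobone_scene"`.
#' @return List with `teeth` (tibble: `tooth_id`, `points`, `confidence`)
#'   and `regions` (tibble: `points`, `confidence`), two regions per tooth.
#' @export
oracle_annotations <- function(scene) {
  polys <- scene_polys(scene)
  teeth <- tibble::tibble(
    tooth_id = purrr::map_chr(polys, "tooth_id"),
    points = purrr::map(polys, "tooth"),
    confidence = 1
  )
  regions <- tibble::tibble(
    points = c(purrr::map(polys, "mesial"), purrr::map(polys, "distal")),
    confidence = 1
  )
  list(teeth = teeth, regions = regions)
}

#' Write a scene's oracle annotations as LabelMe JSON
#'
#' Teeth are labelled `tooth_<FDI>`, regions `cej_bone_region`.
#'
#' @param scene A `"periobone_scene"`.
#' @param path Output `.json` path.
#' @param image_path Value for the LabelMe `imagePath` field.
#' @return `path`, invisibly.
#' @export
write_scene_labelme <- function(scene, path, image_path = "") {
  ann <- oracle_annotations(scene)
  tbl <- new_annotation_tbl(
    label = c(paste0("tooth_", ann$teeth$tooth_id),
              rep("cej_bone_region", nrow(ann$regions))),
    points = c(ann$teeth$points, ann$regions$points),
    image_width = rep(scene$image_width,
                      nrow(ann$teeth) + nrow(ann$regions)),
    image_height = rep(scene$image_height,
                       nrow(ann$teeth) + nrow(ann$regions))
  )
  write_labelme(tbl, path, image_path = image_path)
}

#' Perturb annotations to emulate an imperfect detector
#'
#' Adds independent Gaussian jitter to every vertex and drops whole objects
#' with the given probability; reproducible under `seed`. Zero jitter and
#' zero drop rate is the identity.
#'
#' @param annotations Tibble with a `points` list-column.
#' @param jitter_px Vertex jitter standard deviation, pixels (>= 0).
#' @param drop_rate Per-object drop probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The perturbed tibble.
#' @export
perturb_annotations <- function(annotations, jitter_px = 0, drop_rate = 0,
                                seed = 1L) {
  stopifnot(jitter_px >= 0, drop_rate >= 0, drop_rate <= 1)
  if (jitter_px == 0 && drop_rate == 0) return(annotations)
  withr::with_seed(seed, {
    keep <- stats::runif(nrow(annotations)) >= drop_rate
    out <- annotations[keep, , drop = FALSE]
    if (jitter_px > 0) {
      out$points <- purrr::map(out$points, function(p) {
        p + matrix(stats::rnorm(length(p), 0, jitter_px), nrow(p), 2L)
      })
    }
    out
  })
}
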