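# Percentage alveolar bone loss with the 2 mm biologic-width correction,
# per-site abnormality flagging, and per-tooth worst-site aggregation.

#' Percentage alveolar bone loss at a site
#'
#' Radiographic bone loss relative to the root length, discounting the
#' biologic width (the ~2 mm CEJ-to-crest distance of healthy bone):
#'
#' `percent = 100 * (cej_to_crest_mm - w) / (cej_to_apex_mm - w)`
#'
#' with `w = biologic_width_mm`. Raw values outside `[0, 100]` are clamped —
#' a crest coronal to the biologic-width line is "no loss", a crest at or
#' beyond the apex is total loss — and clamping triggers a warning.
#' Vectorized over sites.
#'
#' @param cej_to_crest_mm CEJ to alveolar-crest distance(s), mm (A to B).
#' @param cej_to_apex_mm CEJ to root-apex distance(s), mm (A to C).
#' @param biologic_width_mm Biologic-width constant, mm (default 2).
#' @return Percent bone loss in `[0, 100]`.
#' @export
#' @examples
#' percent_bone_loss(6, 14)   # (6-2)/(14-2) = 33.33 %
percent_bone_loss <- function(cej_to_crest_mm, cej_to_apex_mm,
                              biologic_width_mm = 2) {
  stopifnot(all(cej_to_crest_mm >= 0), all(cej_to_apex_mm >= 0))
  if (any(cej_to_apex_mm <= biologic_width_mm)) {
    stop(sprintf(
      "degenerate root: CEJ-to-apex distance must exceed the biologic width (%.3g mm)",
      biologic_width_mm), call. = FALSE)
  }
  raw <- 100 * (cej_to_crest_mm - biologic_width_mm) /
    (cej_to_apex_mm - biologic_width_mm)
  clamped <- pmin(pmax(raw, 0), 100)
  n_clamped <- sum(abs(clamped - raw) > 1e-12)
  if (n_clamped > 0L) {
    warning(sprintf("%d bone-loss value(s) outside [0, 100] were clamped",
                    n_clamped), call. = FALSE)
  }
  clamped
}

#' Flag an abnormal CEJ-to-crest gap
#'
#' `TRUE` iff the gap strictly exceeds the threshold (default 2 mm).
#' Vectorized.
#'
#' @inheritParams percent_bone_loss
#' @param threshold_mm Gap threshold, mm (default 2).
#' @return Logical vector.
#' @export
flag_abnormal <- function(cej_to_crest_mm, threshold_mm = 2) {
  cej_to_crest_mm > threshold_mm
}

#' Per-site bone-loss measurement
#'
#' Adds `percent_bone_loss` and `abnormal_flag` columns to a site tibble
#' (see [measure_sites()]).
#'
#' @param sites Tibble with `tooth_id`, `side`, `cej_to_crest_mm`,
#'   `cej_to_apex_mm`.
#' @param biologic_width_mm Biologic-width constant for the formula, mm.
#' @param threshold_mm Abnormality threshold for the gap, mm.
#' @return `sites` with `percent_bone_loss` and `abnormal_flag` appended.
#' @export
measure_bone_loss <- function(sites, biologic_width_mm = 2, threshold_mm = 2) {
  out <- tibble::as_tibble(sites)
  if (nrow(out) == 0L) {
    out$percent_bone_loss <- numeric()
    out$abnormal_flag <- logical()
    return(out)
  }
  out$percent_bone_loss <- percent_bone_loss(
    out$cej_to_crest_mm, out$cej_to_apex_mm, biologic_width_mm)
  out$abnormal_flag <- flag_abnormal(out$cej_to_crest_mm, threshold_mm)
  out
}

#' Aggregate sites to per-tooth bone loss
#'
#' The per-tooth percentage is that of the most severe site (the maximum);
#' bone support is its complement to 100; the abnormality flag is the OR
#' over sites.
#'
#' @param site_results Site tibble from [measure_bone_loss()].
#' @return Per-tooth tibble: `tooth_id`, `n_sites`, `worst_side`,
#'   `percent_bone_loss`, `bone_support_percent`, `abnormal_flag`.
#' @export
aggregate_teeth <- function(site_results) {
  if (nrow(site_results) == 0L) {
    stop("no measured sites: cannot aggregate to teeth", call. = FALSE)
  }
  site_results |>
    dplyr::group_by(.data$tooth_id) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      worst_side = .data$side[which.max(.data$percent_bone_loss)],
      percent_bone_loss = max(.data$percent_bone_loss),
      abnormal_flag = any(.data$abnormal_flag),
      .groups = "drop"
    ) |>
    dplyr::mutate(bone_support_percent = 100 - .data$percent_bone_loss,
                  .after = "percent_bone_loss") |>
    dplyr::arrange(.data$tooth_id)
}

#' Tooth with the greatest bone loss
#'
#' Ties are broken toward the lowest FDI code.
#'
#' @param results Per-tooth tibble from [aggregate_teeth()].
#' @return One-row tibble with `tooth_id` and `percent_bone_loss`.
#' @export
greatest_loss <- function(results) {
  if (nrow(results) == 0L) stop("no per-tooth results", call. = FALSE)
  ord <- order(-results$percent_bone_loss, as.character(results$tooth_id))
  results[ord[1L], c("tooth_id", "percent_bone_loss")]
}
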