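# Per-tooth periodontal prognosis, following the Thai Association of
# Periodontology five-level scheme: the level is set chiefly by the
# percentage of bone support at the most severe site, refined by clinical
# findings (probing depth, mobility, furcation involvement) when available.
#
# Band conventions (the published interval notations overlap at their
# edges; these are this package's documented, gap-free conventions):
#   Good          support > 75
#   Fair / Poor   50 <= support <= 75  (Fair if probing depth < 6 mm)
#   Questionable  25 <= support < 50
#   Hopeless      support < 25
# Clinical columns act as level-wise ceilings: Good requires mobility 0 and
# furcation 0 and probing < 6 mm; Fair allows mobility/furcation up to 1 and
# probing < 6 mm; Poor allows mobility/furcation up to 2; Questionable up to
# 3. A tooth is assigned the most favorable level whose bone-support floor
# and clinical ceilings it satisfies, so clinical violations downgrade to
# the worst fully satisfied row. Absent clinical fields satisfy every row
# (missing data never forces a downgrade).

PROGNOSIS_LEVELS <- c("Good", "Fair", "Poor", "Questionable", "Hopeless")

# Per-level requirements: bone-support floor (strict for Good), probing
# ceiling (Inf = unconstrained), mobility and furcation ceilings.
prognosis_rows <- function() {
  tibble::tibble(
    level = PROGNOSIS_LEVELS,
    support_min = c(75, 50, 50, 25, -Inf),
    support_strict = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    probing_max = c(6, 6, Inf, Inf, Inf),  # strict: probing < 6 mm
    mobility_max = c(0, 1, 2, 3, 3),
    furcation_max = c(0, 1, 2, 3, 3)
  )
}

#' Classify periodontal prognosis from bone support
#'
#' Maps bone support (100 minus percent bone loss, from the most severe
#' site) and optional clinical findings to one of the five prognosis levels
#' (Good, Fair, Poor, Questionable, Hopeless). Without clinical data the
#' classification is radiographic-only: the 50-75 % band reports Fair, with
#' `basis` flagging that probing depth could not be checked. Vectorized over
#' teeth.
#'
#' @param bone_support_percent Bone support in `[0, 100]`.
#' @param probing_depth_mm Probing depth, mm, or `NA` if unknown.
#' @param mobility Tooth mobility grade 0-3, or `NA`.
#' @param furcation Furcation involvement grade 0-3, or `NA`.
#' @return Tibble with `level` (ordered factor, Good > ... > Hopeless) and
#'   `basis` (`"radiographic_only"` or `"radiographic_plus_clinical"`).
#' @export
#' @examples
#' classify_prognosis(c(80, 60, 20))
#' classify_prognosis(60, probing_depth_mm = 7, mobility = 1, furcation = 1)
classify_prognosis <- function(bone_support_percent, probing_depth_mm = NA,
                               mobility = NA, furcation = NA) {
  n <- length(bone_support_percent)
  if (any(is.na(bone_support_percent)) ||
      any(bone_support_percent < 0 | bone_support_percent > 100)) {
    stop("bone_support_percent must lie within [0, 100]", call. = FALSE)
  }
  probing_depth_mm <- rep_len(probing_depth_mm, n)
  mobility <- rep_len(mobility, n)
  furcation <- rep_len(furcation, n)
  if (any(!is.na(mobility) & !(mobility %in% 0:3)) ||
      any(!is.na(furcation) & !(furcation %in% 0:3))) {
    stop("mobility and furcation grades must be in 0..3", call. = FALSE)
  }
  if (any(!is.na(probing_depth_mm) & probing_depth_mm < 0)) {
    stop("probing_depth_mm must be non-negative", call. = FALSE)
  }
  rows <- prognosis_rows()
  level <- character(n)
  for (i in seq_len(n)) {
    s <- bone_support_percent[[i]]
    ok_support <- ifelse(rows$support_strict, s > rows$support_min,
                         s >= rows$support_min)
    ok_probing <- is.na(probing_depth_mm[[i]]) |
      probing_depth_mm[[i]] < rows$probing_max
    ok_mob <- is.na(mobility[[i]]) | mobility[[i]] <= rows$mobility_max
    ok_fur <- is.na(furcation[[i]]) | furcation[[i]] <= rows$furcation_max
    level[[i]] <- rows$level[which(ok_support & ok_probing & ok_mob & ok_fur)[1L]]
  }
  has_clinical <- !is.na(probing_depth_mm) | !is.na(mobility) | !is.na(furcation)
  tibble::tibble(
    level = factor(level, levels = rev(PROGNOSIS_LEVELS), ordered = TRUE),
    basis = ifelse(has_clinical, "radiographic_plus_clinical", "radiographic_only")
  )
}

#' Classify prognosis for every tooth in a result set
#'
#' Joins optional per-tooth clinical findings onto aggregated bone-loss
#' results and fills `prognosis` and `basis` columns. Teeth without a
#' clinical entry are classified radiographically only.
#'
#' @param results Per-tooth tibble from [aggregate_teeth()] (needs
#'   `tooth_id` and `bone_support_percent`).
#' @param clinical Optional tibble: `tooth_id`, `probing_depth_mm`,
#'   `mobility`, `furcation`.
#' @return `results` with `prognosis` (ordered factor) and `basis` appended.
#' @export
classify_dentition <- function(results, clinical = NULL) {
  out <- tibble::as_tibble(results)
  if (nrow(out) == 0L) {
    out$prognosis <- factor(character(), levels = rev(PROGNOSIS_LEVELS),
                            ordered = TRUE)
    out$basis <- character()
    return(out)
  }
  if (is.null(clinical) || nrow(clinical) == 0L) {
    cl <- tibble::tibble(probing_depth_mm = rep(NA_real_, nrow(out)),
                         mobility = NA_real_, furcation = NA_real_)
  } else {
    cl <- dplyr::left_join(
      out["tooth_id"],
      dplyr::mutate(tibble::as_tibble(clinical),
                    tooth_id = as.character(.data$tooth_id)),
      by = "tooth_id"
    )
  }
  cls <- classify_prognosis(out$bone_support_percent,
                            probing_depth_mm = cl$probing_depth_mm,
                            mobility = cl$mobility,
                            furcation = cl$furcation)
  out$prognosis <- cls$level
  out$basis <- cls$basis
  out
}
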