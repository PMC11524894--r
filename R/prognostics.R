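#' Explainable prognostic parameters from a tissue mask
#'
#' Computes the four quantitative prognostic parameters of the platform from
#' a single mask:
#'
#' * **TLS-TD** — TLS tumor density: qualified TLS area (intratumoral +
#'   immediate peritumoral objects) divided by tumor + tumor-stroma area;
#' * **NECR-TD** — necrosis tumor density: tumor-associated necrosis area
#'   over the same denominator;
#' * **T/NR** — the simple ratio of qualified TLS area to tumor-associated
#'   necrosis area, with no further normalization; undefined (`NA`) when the
#'   necrosis area is zero;
#' * the cumulative **T+NR** group (PG1-PG3) is assigned later, from
#'   cohort-level dichotomized TLS-TD and NECR-TD
#'   ([assign_prognostic_group()]).
#'
#' Object qualification follows [qualify_objects()]; no size filtering is
#' applied anywhere. Ratios use pixel areas (µm² gives identical ratios).
#' A mask with zero tumor + tumor-stroma area yields `NA` densities with
#' `evaluable = FALSE` (a slide without evaluable tumor, not an error).
#'
#' @param mask A [tissue_mask()].
#' @param peritumoral_dist_um Qualification distance in µm (default 250).
#' @param connectivity Component/adjacency connectivity, 8 (default) or 4.
#' @return A one-row tibble: `slide_id`, `tumor_px`, `tu_stroma_px`,
#'   `tls_area_px` (qualified), `necrosis_area_px` (tumor-associated),
#'   `tls_td`, `necr_td`, `t_nr`, `n_tls_objects`, `n_necrosis_objects`,
#'   `evaluable`, `peritumoral_dist_um`, `connectivity`.
#' @examples
#' # tls_td of 9 TLS px against 60 tumor + 30 stroma px is 0.1
#' @export
prognostic_scores <- function(mask, peritumoral_dist_um = 250,
                              connectivity = 8) {
  stopifnot(inherits(mask, "tissue_mask"))
  prof <- profile_areas(mask)
  px <- setNames(prof$pixels, prof$class_name)
  denom <- px[["TUMOR"]] + px[["TU_STROMA"]]

  tls <- qualified_area(mask, "TLS", peritumoral_dist_um, connectivity)
  necr <- qualified_area(mask, "NECROSIS", peritumoral_dist_um, connectivity)

  tibble(
    slide_id = mask$slide_id %||% NA_character_,
    tumor_px = px[["TUMOR"]],
    tu_stroma_px = px[["TU_STROMA"]],
    tls_area_px = tls$area,
    necrosis_area_px = necr$area,
    n_tls_objects = tls$n_objects,
    n_necrosis_objects = necr$n_objects,
    tls_td = if (denom > 0) tls$area / denom else NA_real_,
    necr_td = if (denom > 0) necr$area / denom else NA_real_,
    t_nr = if (necr$area > 0) tls$area / necr$area else NA_real_,
    evaluable = denom > 0,
    peritumoral_dist_um = peritumoral_dist_um,
    connectivity = as.integer(connectivity)
  )
}

qualified_area <- function(mask, class_name, peritumoral_dist_um,
                           connectivity) {
  obj <- extract_objects(mask, class_name, connectivity)
  if (nrow(obj) == 0) return(list(area = 0L, n_objects = 0L))
  obj <- qualify_objects(obj, mask, peritumoral_dist_um, connectivity)
  keep <- obj$qualification %in% c("intratumoral", "peritumoral")
  list(area = sum(obj$area_px[keep]), n_objects = sum(keep))
}

#' Dichotomize a parameter at a cutoff
#'
#' @param values Numeric vector.
#' @param cutoff Cutoff value; values strictly above it are `"high"`.
#' @return Factor with levels `low`, `high` (`NA` stays `NA`).
#' @export
dichotomize <- function(values, cutoff) {
  factor(ifelse(values > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Cumulative T+NR prognostic group
#'
#' Combines the dichotomized TLS-TD and NECR-TD of a case into one of three
#' prognostic groups: PG1 (TLS high / necrosis low — both favorable), PG3
#' (TLS low / necrosis high — both adverse), PG2 for the two mixed
#' combinations. TLS density is protective and necrosis density adverse, so
#' the four input combinations collapse onto exactly three outcome levels.
#'
#' @param tls_group,necr_group Vectors with values `"low"`/`"high"` (factors
#'   from [dichotomize()] work as-is).
#' @return Factor with levels `PG1`, `PG2`, `PG3`.
#' @examples
#' assign_prognostic_group(c("high", "low"), c("low", "high"))  # PG1, PG3
#' @export
assign_prognostic_group <- function(tls_group, necr_group) {
  tls_group <- as.character(tls_group)
  necr_group <- as.character(necr_group)
  ok <- function(x) x %in% c("low", "high") | is.na(x)
  if (!all(ok(tls_group)) || !all(ok(necr_group))) {
    abort("groups must be 'low' or 'high'", class = "tissuemaps_value_error")
  }
  if (length(tls_group) != length(necr_group)) {
    abort("tls_group and necr_group lengths differ",
          class = "tissuemaps_value_error")
  }
  pg <- dplyr::case_when(
    is.na(tls_group) | is.na(necr_group) ~ NA_character_,
    tls_group == "high" & necr_group == "low" ~ "PG1",
    tls_group == "low" & necr_group == "high" ~ "PG3",
    TRUE ~ "PG2"
  )
  factor(pg, levels = c("PG1", "PG2", "PG3"))
}

#' Score a cohort of masks
#'
#' Maps [prognostic_scores()] over a manifest of per-case masks, pooling
#' multiple slides of a case by summing raw areas before forming ratios
#' (area weighting, consistent with case-level subtype aggregation).
#'
#' @param scores Tibble of per-slide rows from [prognostic_scores()] with a
#'   `case_id` column.
#' @return One row per case with pooled areas and recomputed densities.
#' @export
pool_case_scores <- function(scores) {
  stopifnot("case_id" %in% names(scores))
  scores |>
    group_by(.data$case_id) |>
    summarise(
      tumor_px = sum(.data$tumor_px),
      tu_stroma_px = sum(.data$tu_stroma_px),
      tls_area_px = sum(.data$tls_area_px),
      necrosis_area_px = sum(.data$necrosis_area_px),
      n_tls_objects = sum(.data$n_tls_objects),
      n_necrosis_objects = sum(.data$n_necrosis_objects),
      .groups = "drop"
    ) |>
    mutate(
      denom = .data$tumor_px + .data$tu_stroma_px,
      tls_td = ifelse(.data$denom > 0, .data$tls_area_px / .data$denom, NA_real_),
      necr_td = ifelse(.data$denom > 0, .data$necrosis_area_px / .data$denom, NA_real_),
      t_nr = ifelse(.data$necrosis_area_px > 0,
                    .data$tls_area_px / .data$necrosis_area_px, NA_real_),
      evaluable = .data$denom > 0
    ) |>
    select(-"denom")
}
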