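#' Legend for the LUAD/LUSC subtype scheme
#'
#' The subtyping layer works with six classes: TUMOR_LUAD, TUMOR_LUSC, tumor
#' stroma, necrosis, mucin and background. Subtype labels are only
#' interpreted inside pixels the main tissue mask calls TUMOR (epithelial
#' tumor component); the non-tumor classes exist to give the subtype model
#' context and are ignored in the LUAD/LUSC tally.
#'
#' @return A [class_legend()] with 6 entries.
#' @export
subtype_legend <- function() {
  class_legend(tibble(
    class_id = 0:5,
    class_name = c("BACK", "TUMOR_LUAD", "TUMOR_LUSC", "TU_STROMA",
                   "NECROSIS", "MUCIN"),
    group = c("background", "tumor_region", "tumor_region", "tumor_region",
              "tumor_region", "tumor_region"),
    color = c("#FFFFFF", "#2CA02C", "#D62728", "#FF9896", "#1F3A93", "#17BECF")
  ))
}

#' Tumor support for subtype evaluation
#'
#' Returns the binary support on which all subtype tallies run: the pixels
#' the main mask calls TUMOR. The subtype model is applied only to regions
#' recognized as epithelial tumor component by the main algorithm, so
#' subtype labels outside this support are ignored, never reassigned.
#'
#' @param main The main [tissue_mask()] (11-class legend).
#' @param subtype Optional subtype [tissue_mask()]; when given, its geometry
#'   is checked against `main`.
#' @return A logical matrix.
#' @export
restrict_to_tumor <- function(main, subtype = NULL) {
  stopifnot(inherits(main, "tissue_mask"))
  if (!is.null(subtype) &&
      !identical(dim(main$labels), dim(subtype$labels))) {
    abort("main and subtype masks have different dimensions",
          class = "tissuemaps_shape_error")
  }
  main$labels == legend_id(main$legend, "TUMOR")
}

#' Slide-level LUAD/LUSC call from area percentages
#'
#' Tallies LUAD- and LUSC-labeled pixels over the tumor support of the main
#' mask and classifies the slide by the dominant area percentage:
#' `pct_luad = 100 |LUAD| / (|LUAD| + |LUSC|)`. Slides whose winning
#' percentage falls in the closed borderline zone (default 40-60%) are
#' flagged for review — such tumors are typically poorly differentiated and
#' need immunohistochemistry. An exact 50/50 tie is called LUAD with
#' `borderline = TRUE` and a warning; a slide with no evaluable tumor pixels
#' yields an explicit `"no_tumor"` call rather than an error.
#'
#' @param main Main [tissue_mask()] (11-class legend).
#' @param subtype Subtype [tissue_mask()] ([subtype_legend()]), same geometry.
#' @param borderline Closed interval (length 2, percent) flagging borderline
#'   winning percentages.
#' @return A one-row tibble: `slide_id`, `level`, `n_luad`, `n_lusc`,
#'   `pct_luad`, `pct_lusc`, `call`, `borderline`, `mucin_pct`, plus the raw
#'   mucin tallies used by case aggregation.
#' @examples
#' # 70% LUAD tumor area -> confident LUAD call
#' @export
classify_slide <- function(main, subtype, borderline = c(40, 60)) {
  support <- restrict_to_tumor(main, subtype)
  sl <- subtype$labels
  lg <- subtype$legend
  n_luad <- sum(sl[support] == legend_id(lg, "TUMOR_LUAD"))
  n_lusc <- sum(sl[support] == legend_id(lg, "TUMOR_LUSC"))
  mucin <- mucin_tallies(subtype, main)
  call_from_counts(n_luad, n_lusc, mucin,
                   slide_id = main$slide_id %||% NA_character_,
                   level = "slide", borderline = borderline)
}

call_from_counts <- function(n_luad, n_lusc, mucin, slide_id, level,
                             borderline = c(40, 60)) {
  base <- tibble(
    slide_id = slide_id, level = level,
    n_luad = n_luad, n_lusc = n_lusc,
    n_mucin = mucin$n_mucin, n_mucin_denom = mucin$n_denom
  )
  if (n_luad + n_lusc == 0) {
    return(mutate(base, pct_luad = NA_real_, pct_lusc = NA_real_,
                  call = "no_tumor", borderline = NA,
                  mucin_pct = mucin_pct_from(mucin)))
  }
  pct_luad <- 100 * n_luad / (n_luad + n_lusc)
  if (pct_luad == 50) {
    warn(paste0("exact 50/50 LUAD/LUSC tie on ", level, " ",
                slide_id, "; calling LUAD, flagged borderline"))
  }
  call <- if (pct_luad >= 50) "LUAD" else "LUSC"
  winner <- max(pct_luad, 100 - pct_luad)
  mutate(base,
         pct_luad = pct_luad, pct_lusc = 100 - pct_luad, call = call,
         borderline = winner >= borderline[1] & winner <= borderline[2],
         mucin_pct = mucin_pct_from(mucin))
}

mucin_tallies <- function(subtype, main) {
  region <- main$labels %in% legend_id(main$legend,
                                       tumor_region_classes(main$legend))
  sl <- subtype$labels[region]
  lg <- subtype$legend
  n_mucin <- sum(sl == legend_id(lg, "MUCIN"))
  n_tumor <- sum(sl %in% legend_id(lg, c("TUMOR_LUAD", "TUMOR_LUSC")))
  n_stroma <- sum(sl == legend_id(lg, "TU_STROMA"))
  list(n_mucin = n_mucin, n_denom = n_mucin + n_tumor + n_stroma)
}

mucin_pct_from <- function(mucin) {
  if (mucin$n_denom == 0) NA_real_ else 100 * mucin$n_mucin / mucin$n_denom
}

#' Mucin fraction of the tumor
#'
#' Percentage of mucin within the tumor:
#' `100 * area_mucin / (area_mucin + area_tumor + area_tumor_stroma)`,
#' tallied from the subtype labels inside the main mask's tumor region. A
#' high value points the pathologist to mucinous/colloid adenocarcinoma; the
#' percentage is reported without a diagnostic threshold.
#'
#' @inheritParams classify_slide
#' @return A percentage in `[0, 100]`, or `NA` when the tumor denominator is
#'   empty (no-tumor outcome).
#' @export
mucin_fraction <- function(subtype, main) {
  if (!identical(dim(main$labels), dim(subtype$labels))) {
    abort("main and subtype masks have different dimensions",
          class = "tissuemaps_shape_error")
  }
  mucin_pct_from(mucin_tallies(subtype, main))
}

#' Case-level subtype call from multiple slides
#'
#' Pools the raw LUAD/LUSC (and mucin) pixel tallies across a case's slides
#' — area weighting, so a large tumor-rich slide outweighs a sliver — and
#' classifies the pooled counts exactly as [classify_slide()] does. With a
#' single slide the case call equals the slide call; slide order never
#' matters.
#'
#' @param slide_calls Tibble of slide-level rows from [classify_slide()]
#'   (several cases may be mixed when `case_id` is present).
#' @param case_id Optional case identifier stored on the output.
#' @param borderline Borderline zone, as in [classify_slide()].
#' @return A one-row tibble per case with `level = "case"`.
#' @export
aggregate_case <- function(slide_calls, case_id = NULL, borderline = c(40, 60)) {
  stopifnot(is.data.frame(slide_calls), nrow(slide_calls) >= 1)
  mucin <- list(n_mucin = sum(slide_calls$n_mucin),
                n_denom = sum(slide_calls$n_mucin_denom))
  out <- call_from_counts(sum(slide_calls$n_luad), sum(slide_calls$n_lusc),
                          mucin,
                          slide_id = case_id %||% NA_character_,
                          level = "case", borderline = borderline)
  dplyr::rename(out, case_id = "slide_id")
}
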