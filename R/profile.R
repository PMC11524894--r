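#' Per-class area profile of a tissue mask
#'
#' Counts the pixels of every legend class inside a region (the whole mask by
#' default) and converts counts to areas: `area_um2 = pixels * mpp^2`. The
#' profile is the substrate for every downstream area term (tumor area,
#' necrosis area, TLS area, ...).
#'
#' @param mask A [tissue_mask()].
#' @param restrict_to Optional logical (or 0/1) matrix with the same
#'   dimensions as the mask; only `TRUE` pixels are counted.
#' @return A tibble with one row per legend class: `slide_id`, `class_id`,
#'   `class_name`, `group`, `pixels`, `area_um2`. Classes absent from the
#'   region get zero rows, so the column sums are conserved:
#'   `sum(pixels)` equals the region size (full raster if unrestricted).
#' @examples
#' m <- tissue_mask(matrix(c(1L, 1L, 2L, 0L), 2, 2), default_legend(), mpp = 2)
#' profile_areas(m)
#' @export
profile_areas <- function(mask, restrict_to = NULL) {
  stopifnot(inherits(mask, "tissue_mask"))
  labels <- mask$labels
  if (!is.null(restrict_to)) {
    if (!identical(dim(restrict_to), dim(labels))) {
      abort(sprintf("restrict_to is %s but mask is %s",
                    paste(dim(restrict_to), collapse = "x"),
                    paste(dim(labels), collapse = "x")),
            class = "tissuemaps_shape_error")
    }
    labels <- labels[as.logical(restrict_to)]
  }
  legend <- mask$legend
  counts <- tabulate(labels + 1L, nbins = max(legend$class_id) + 1L)
  tibble(
    slide_id = mask$slide_id %||% NA_character_,
    class_id = legend$class_id,
    class_name = legend$class_name,
    group = legend$group,
    pixels = counts[legend$class_id + 1L],
    area_um2 = counts[legend$class_id + 1L] * mask$mpp^2
  )
}

#' Write an area profile to CSV
#'
#' @param profile Tibble from [profile_areas()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_csv(profile, path)
  invisible(path)
}
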