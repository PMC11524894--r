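#' Extract connected tissue objects of a class
#'
#' Connected-component labeling of one class of the mask (8-neighborhood by
#' default, configurable to 4). Deliberately no filtering of any kind:
#' single-pixel objects are kept, matching the no-filtering policy of the
#' quantification layer.
#'
#' @param mask A [tissue_mask()].
#' @param class_name A legend class, typically `"TLS"` or `"NECROSIS"`.
#' @param connectivity 8 (default) or 4.
#' @return A tibble with one row per object: `object_id`, `class_name`,
#'   `area_px`, `area_um2` and a `pixels` list-column of linear (column-major)
#'   raster indices.
#' @export
extract_objects <- function(mask, class_name, connectivity = 8) {
  stopifnot(inherits(mask, "tissue_mask"))
  id <- legend_id(mask$legend, class_name)
  lab <- cc_label(mask$labels == id, as.integer(connectivity))
  k <- max(lab)
  if (k == 0) {
    return(tibble(object_id = integer(), class_name = character(),
                  area_px = integer(), area_um2 = numeric(),
                  pixels = list()))
  }
  pix <- split(which(lab > 0), lab[lab > 0])
  tibble(
    object_id = seq_len(k),
    class_name = class_name,
    area_px = unname(lengths(pix)),
    area_um2 = unname(lengths(pix)) * mask$mpp^2,
    pixels = unname(pix)
  )
}

#' Tumor-region support of a mask
#'
#' Logical raster of the tumor region: the union of the four tumor-region
#' legend classes (TUMOR, TU_STROMA, NECROSIS, MUCIN by default).
#'
#' @param mask A [tissue_mask()].
#' @param exclude Classes to drop from the union (used when qualifying
#'   objects of a class that is itself part of the tumor region).
#' @return A logical matrix.
#' @export
tumor_region_mask <- function(mask, exclude = character()) {
  classes <- setdiff(tumor_region_classes(mask$legend), exclude)
  matrix(mask$labels %in% legend_id(mask$legend, classes),
         nrow = nrow(mask$labels))
}

#' Qualify tissue objects by relation to the tumor region
#'
#' Assigns each object one of three qualifications relative to the tumor
#' region (TUMOR ∪ TU_STROMA ∪ NECROSIS ∪ MUCIN, minus the object's own
#' class):
#'
#' * `intratumoral` — some pixel of the object touches the tumor region
#'   (Euclidean center distance ≤ 1 for 4-connectivity, ≤ √2 for 8);
#' * `peritumoral` — minimum boundary distance ≤ `peritumoral_dist_um`
#'   (default 250 µm, "immediate peritumoral");
#' * `non_tumor_associated` — farther away; excluded from every density.
#'
#' Both intratumoral and peritumoral TLS count toward TLS density; for
#' necrosis the same rule defines "tumor-associated", with necrosis inside
#' the tumor bed captured by adjacency.
#'
#' @param objects Tibble from [extract_objects()].
#' @param mask The [tissue_mask()] the objects came from.
#' @param peritumoral_dist_um Distance threshold in microns (≥ 0).
#' @param connectivity Adjacency rule for "touching", 8 (default) or 4.
#' @return `objects` with `qualification` and `min_dist_um` columns;
#'   `min_dist_um` is the minimum pixel-center distance to the tumor region
#'   (0 would mean overlap, which cannot happen since classes are disjoint).
#' @export
qualify_objects <- function(objects, mask, peritumoral_dist_um = 250,
                            connectivity = 8) {
  stopifnot(inherits(mask, "tissue_mask"), peritumoral_dist_um >= 0)
  if (nrow(objects) == 0) {
    return(mutate(objects, qualification = character(),
                  min_dist_um = numeric()))
  }
  touch_px <- if (connectivity == 8) sqrt(2) else 1
  dist_px <- distance_to_tumor(mask, exclude = unique(objects$class_name))
  min_d <- map_dbl(objects$pixels, function(p) min(dist_px[p]))
  min_um <- min_d * mask$mpp
  qual <- dplyr::case_when(
    min_d <= touch_px + 1e-9 ~ "intratumoral",
    min_um <= peritumoral_dist_um + 1e-9 ~ "peritumoral",
    TRUE ~ "non_tumor_associated"
  )
  mutate(objects, qualification = qual, min_dist_um = min_um)
}

# Exact Euclidean distance (in px) of every pixel to the nearest
# tumor-region pixel; Inf everywhere when the reference region is empty.
distance_to_tumor <- function(mask, exclude = character()) {
  region <- tumor_region_mask(mask, exclude = exclude)
  if (!any(region)) {
    return(matrix(Inf, nrow(region), ncol(region)))
  }
  # distmap(x): distance of foreground (non-zero) pixels of x to the nearest
  # background pixel; with x = !region the background is the tumor region.
  d <- EBImage::distmap(matrix(as.numeric(!region), nrow(region)))
  matrix(as.numeric(d), nrow(region))
}
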