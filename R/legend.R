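#' Tissue class legends
#'
#' A class legend maps the integer values of a label raster to named tissue
#' classes and assigns each class to one of three groups:
#' `"tumor_region"` (epithelial tumor, tumor stroma, necrosis, mucin),
#' `"benign"` (everything else on the slide) and `"background"` (exactly one
#' class, the glass background of the scan). Class ids must be unique and
#' contiguous from 0 so that a raster can be validated cheaply.
#'
#' `default_legend()` is the 11-tissue-class (+ background) scheme used by the
#' whole-slide segmentation workflow:
#' TUMOR (epithelial tumor component), TU_STROMA (tumor stroma), NECROSIS
#' (necrotic debris), MUCIN, TLS (lymphatic tissue / tertiary lymphoid
#' structures), LUNG_BENIGN (tumor-free lung parenchyma), STROMA
#' (non-tumor-associated stroma, fat, vessels, muscle), BRONCH (bronchial
#' mucosa), BLOOD, GLAND_PERIBR (peribronchial mucous glands), CARTIL
#' (cartilage) and BACK (slide background).
#'
#' `annotation_legend()` is the finer 14-tissue-class scheme used at
#' annotation time, in which the connective-tissue compartment is split into
#' four classes (CONN_STROMA, FAT, MUSCLE, VESSEL).
#' `merge_connective_classes()` collapses those four into the single STROMA
#' class, which reproduces the 11-class training scheme.
#'
#' @param entries A data frame with columns `class_id`, `class_name`, `group`
#'   and optionally `color` (hex string used by plotting helpers).
#' @return A `class_legend`: a tibble with one row per class.
#' @examples
#' default_legend()
#' n_tissue_classes(merge_connective_classes(annotation_legend()))
#' @export
class_legend <- function(entries) {
  entries <- as_tibble(entries)
  required <- c("class_id", "class_name", "group")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort(paste0("legend is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tissuemaps_legend_error")
  }
  if (!"color" %in% names(entries)) entries$color <- NA_character_
  entries <- entries[, c("class_id", "class_name", "group", "color")]
  entries$class_id <- as.integer(entries$class_id)
  entries$class_name <- as.character(entries$class_name)
  entries$group <- as.character(entries$group)
  entries <- arrange(entries, .data$class_id)
  validate_legend(entries)
  structure(entries, class = c("class_legend", class(tibble())))
}

validate_legend <- function(entries) {
  if (anyDuplicated(entries$class_id)) {
    dup <- entries$class_id[duplicated(entries$class_id)][1]
    abort(paste0("duplicate class_id in legend: ", dup),
          class = "tissuemaps_legend_error")
  }
  if (anyDuplicated(entries$class_name)) {
    dup <- entries$class_name[duplicated(entries$class_name)][1]
    abort(paste0("duplicate class_name in legend: ", dup),
          class = "tissuemaps_legend_error")
  }
  if (!identical(sort(entries$class_id), seq_len(nrow(entries)) - 1L)) {
    abort(paste0("class_ids must be contiguous from 0; got {",
                 paste(sort(entries$class_id), collapse = ","), "}"),
          class = "tissuemaps_legend_error")
  }
  bad_group <- setdiff(unique(entries$group),
                       c("tumor_region", "benign", "background"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown legend group: ", bad_group[1]),
          class = "tissuemaps_legend_error")
  }
  if (sum(entries$group == "background") != 1L) {
    abort("legend must declare exactly one background class",
          class = "tissuemaps_legend_error")
  }
  invisible(entries)
}

#' @rdname class_legend
#' @export
default_legend <- function() {
  class_legend(tibble(
    class_id = 0:11,
    class_name = c("BACK", "TUMOR", "TU_STROMA", "NECROSIS", "MUCIN", "TLS",
                   "LUNG_BENIGN", "STROMA", "BRONCH", "BLOOD",
                   "GLAND_PERIBR", "CARTIL"),
    group = c("background", "tumor_region", "tumor_region", "tumor_region",
              "tumor_region", "benign", "benign", "benign", "benign",
              "benign", "benign", "benign"),
    color = c("#FFFFFF", "#D62728", "#FF9896", "#1F3A93", "#17BECF",
              "#FFD700", "#98DF8A", "#C49C94", "#9467BD", "#8C1717",
              "#E377C2", "#7F7F7F")
  ))
}

#' @rdname class_legend
#' @export
annotation_legend <- function() {
  class_legend(tibble(
    class_id = 0:14,
    class_name = c("BACK", "TUMOR", "TU_STROMA", "NECROSIS", "MUCIN", "TLS",
                   "LUNG_BENIGN", "CONN_STROMA", "FAT", "MUSCLE", "VESSEL",
                   "BRONCH", "BLOOD", "GLAND_PERIBR", "CARTIL"),
    group = c("background", "tumor_region", "tumor_region", "tumor_region",
              "tumor_region", "benign", "benign", "benign", "benign",
              "benign", "benign", "benign", "benign", "benign", "benign")
  ))
}

#' @rdname class_legend
#' @param legend A `class_legend` containing the four connective-tissue
#'   classes CONN_STROMA, FAT, MUSCLE and VESSEL.
#' @export
merge_connective_classes <- function(legend) {
  connective <- c("CONN_STROMA", "FAT", "MUSCLE", "VESSEL")
  if (!all(connective %in% legend$class_name)) {
    abort("legend does not contain the four connective-tissue classes",
          class = "tissuemaps_legend_error")
  }
  keep <- legend[!legend$class_name %in% connective, ]
  merged <- bind_rows(
    keep[, c("class_name", "group")],
    tibble(class_name = "STROMA", group = "benign")
  )
  # renumber contiguously, background first for the conventional 0 id
  merged <- merged[order(merged$group != "background"), ]
  merged$class_id <- seq_len(nrow(merged)) - 1L
  class_legend(merged)
}

#' @rdname class_legend
#' @export
n_tissue_classes <- function(legend) {
  sum(legend$group != "background")
}

#' Read a class legend from a YAML or JSON config file
#'
#' The config holds a list of entries, each with `id`, `name`, `group` and an
#' optional `color`, and may carry a top-level default `mpp` (microns per
#' pixel) that [read_mask()] uses when the caller supplies none.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` legend config.
#' @return A `class_legend`; the config's `mpp`, if present, is attached as
#'   attribute `"mpp"`.
#' @export
load_legend <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("legend config not found: ", path),
          class = "tissuemaps_legend_error")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$classes)) {
    abort(paste0("legend config has no 'classes' entry: ", path),
          class = "tissuemaps_legend_error")
  }
  rows <- map(cfg$classes, function(e) {
    if (is.null(e$id) || is.null(e$name) || is.null(e$group)) {
      abort(paste0("malformed legend entry (need id/name/group): ",
                   paste(deparse(e), collapse = "")),
            class = "tissuemaps_legend_error")
    }
    tibble(class_id = as.integer(e$id), class_name = as.character(e$name),
           group = as.character(e$group),
           color = if (is.null(e$color)) NA_character_ else as.character(e$color))
  })
  legend <- class_legend(bind_rows(rows))
  if (!is.null(cfg$mpp)) attr(legend, "mpp") <- as.numeric(cfg$mpp)
  legend
}

#' Write a class legend to a YAML config file
#'
#' @param legend A `class_legend`.
#' @param path Output path (`.yaml`).
#' @param mpp Optional default microns-per-pixel to store in the config.
#' @return `path`, invisibly.
#' @export
write_legend <- function(legend, path, mpp = NULL) {
  cfg <- list(classes = purrr::pmap(legend, function(class_id, class_name,
                                                     group, color) {
    e <- list(id = class_id, name = class_name, group = group)
    if (!is.na(color)) e$color <- color
    e
  }))
  if (!is.null(mpp)) cfg$mpp <- mpp
  yaml::write_yaml(cfg, path)
  invisible(path)
}

legend_id <- function(legend, class_name) {
  i <- match(class_name, legend$class_name)
  if (anyNA(i)) {
    abort(paste0("class not in legend: ",
                 paste(class_name[is.na(i)], collapse = ", ")),
          class = "tissuemaps_legend_error")
  }
  legend$class_id[i]
}

tumor_region_classes <- function(legend) {
  legend$class_name[legend$group == "tumor_region"]
}
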