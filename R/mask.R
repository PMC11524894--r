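#' Tissue label masks
#'
#' A `tissue_mask` bundles a 2-D integer label raster with its class legend
#' and pixel resolution. Rasters are indexed `[row, col]`, 0-based offsets in
#' tile grids, and every raster value must be a `class_id` of the legend.
#'
#' @param labels Integer matrix of class ids.
#' @param legend A [class_legend()].
#' @param mpp Microns per pixel (> 0). The platform geometry assumes
#'   segmentation at MPP 1.0 (roughly 10x magnification).
#' @param slide_id Optional slide identifier carried into tabular outputs.
#' @return A `tissue_mask` object.
#' @examples
#' m <- tissue_mask(matrix(0L, 8, 8), default_legend())
#' dim(m)
#' @export
tissue_mask <- function(labels, legend, mpp = 1.0, slide_id = NULL) {
  if (!is.matrix(labels)) {
    abort("labels must be a matrix", class = "tissuemaps_mask_error")
  }
  if (any(dim(labels) <= 0)) {
    abort("raster dimensions must be positive", class = "tissuemaps_mask_error")
  }
  if (!is.numeric(mpp) || length(mpp) != 1 || is.na(mpp) || mpp <= 0) {
    abort("mpp must be a positive number", class = "tissuemaps_mask_error")
  }
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) {
    abort("labels contain NA", class = "tissuemaps_mask_error")
  }
  legend <- as_legend(legend)
  bad <- setdiff(unique(as.vector(labels)), legend$class_id)
  if (length(bad) > 0) {
    abort(paste0("raster contains value(s) not in legend: ",
                 paste(sort(bad), collapse = ", ")),
          class = "tissuemaps_mask_error")
  }
  structure(
    list(labels = labels, legend = legend, mpp = as.numeric(mpp),
         slide_id = slide_id),
    class = "tissue_mask"
  )
}

as_legend <- function(legend) {
  if (inherits(legend, "class_legend")) return(legend)
  class_legend(legend)
}

#' @export
dim.tissue_mask <- function(x) dim(x$labels)

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d px @ %.3g um/px%s\n",
              nrow(x$labels), ncol(x$labels), x$mpp,
              if (is.null(x$slide_id)) "" else paste0("  [", x$slide_id, "]")))
  present <- sort(unique(as.vector(x$labels)))
  cat("  classes present:",
      paste(x$legend$class_name[match(present, x$legend$class_id)],
            collapse = ", "), "\n")
  invisible(x)
}

#' Read and write label masks
#'
#' Masks are stored as single-channel 8-bit PNG or TIFF rasters whose pixel
#' values are the legend's class ids. No palette or RGB encoding is used:
#' value 3 means class id 3.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param legend A [class_legend()] (or the return of [load_legend()]; a
#'   legend-attached default `mpp` is used when `mpp` is `NULL`).
#' @param mpp Microns per pixel; defaults to the legend's stored `mpp` or 1.0.
#' @param slide_id Optional slide identifier.
#' @return `read_mask()` returns a [tissue_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, legend, mpp = NULL, slide_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("mask file not found: ", path),
          class = "tissuemaps_io_error")
  }
  legend <- as_legend_keep_mpp(legend)
  if (is.null(mpp)) mpp <- attr(legend, "mpp") %||% 1.0
  vals <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path) * 255)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (!is.integer(img) && max(img) <= 1) img <- round(img * 255)
    img
  } else {
    abort(paste0("unsupported mask format: ", path),
          class = "tissuemaps_io_error")
  }
  if (length(dim(vals)) == 3) vals <- vals[, , 1]  # collapse grey-stored-as-RGB
  labels <- matrix(as.integer(vals), nrow = nrow(vals))
  tissue_mask(labels, legend, mpp = mpp, slide_id = slide_id)
}

as_legend_keep_mpp <- function(legend) {
  mpp <- attr(legend, "mpp")
  out <- as_legend(legend)
  attr(out, "mpp") <- mpp
  out
}

#' @rdname read_mask
#' @param mask A [tissue_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  if (max(mask$labels) > 255) {
    abort("class ids above 255 cannot be stored as 8-bit rasters",
          class = "tissuemaps_io_error")
  }
  img <- mask$labels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, path, bits.per.sample = 8, compression = "none")
  } else {
    abort(paste0("unsupported mask format: ", path),
          class = "tissuemaps_io_error")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
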