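#' Plan an exact-cover tile grid
#'
#' Whole-slide rasters are processed in non-overlapping tiles of at most
#' `tile_size` px per side (default 512, the inference geometry of the
#' segmentation workflow at MPP 1.0). Edge tiles are ragged — smaller than
#' `tile_size` — rather than padded, so the tiles cover the raster exactly
#' once.
#'
#' @param height,width Raster extent in pixels (> 0).
#' @param tile_size Maximum tile side in pixels (> 0).
#' @return A tibble with one row per tile: `tile_id`, `row_off`, `col_off`
#'   (0-based offsets), `height`, `width`.
#' @examples
#' plan_grid(700, 512)          # 512x512 tile plus a 188x512 remainder
#' @export
plan_grid <- function(height, width, tile_size = 512) {
  if (any(c(height, width, tile_size) <= 0) ||
      any(c(height, width, tile_size) %% 1 != 0)) {
    abort("height, width and tile_size must be positive integers",
          class = "tissuemaps_value_error")
  }
  row_off <- seq(0L, height - 1L, by = tile_size)
  col_off <- seq(0L, width - 1L, by = tile_size)
  grid <- tidyr::expand_grid(row_off = as.integer(row_off),
                             col_off = as.integer(col_off))
  mutate(grid,
         height = pmin(as.integer(tile_size), as.integer(height) - .data$row_off),
         width = pmin(as.integer(tile_size), as.integer(width) - .data$col_off),
         tile_id = row_number(), .before = 1)
}

#' Stand-in segmenters
#'
#' The trained neural segmenter is not part of this package; the inference
#' harness instead takes any callable that maps a tile to a label raster of
#' identical height/width over the legend's class ids. Two deterministic
#' stand-ins ship for testing the harness end to end:
#'
#' * `segmenter_identity()` passes a label tile through unchanged, so
#'   stitched output must equal the input mask exactly.
#' * `segmenter_threshold(legend, n_bins)` bins a numeric intensity tile
#'   (values in `[0, 1]`) into the first `n_bins` class ids by fixed
#'   equal-width thresholds — a per-pixel, tile-independent rule, so tiled
#'   and whole-image application must agree bit-exactly.
#'
#' @param legend A [class_legend()].
#' @param n_bins Number of classes to use (defaults to all legend classes).
#' @return A function `tile -> integer label matrix`.
#' @export
segmenter_identity <- function() {
  function(tile) {
    labels <- tile
    storage.mode(labels) <- "integer"
    labels
  }
}

#' @rdname segmenter_identity
#' @export
segmenter_threshold <- function(legend, n_bins = nrow(legend)) {
  ids <- sort(legend$class_id)[seq_len(n_bins)]
  force(ids)
  function(tile) {
    bin <- pmin(pmax(floor(tile * length(ids)), 0), length(ids) - 1)
    matrix(ids[bin + 1L], nrow = nrow(tile))
  }
}

#' Run tiled inference and stitch a whole-slide mask
#'
#' Applies a segmenter tile by tile over `grid` and places each tile's output
#' verbatim into the stitched raster. No post-filtering or smoothing of any
#' kind is applied after stitching, so for any deterministic per-pixel
#' segmenter the tiled result equals whole-image application.
#'
#' An optional overlap mode (`overlap_px > 0`) reads context-expanded tiles
#' and center-crops the segmenter output back to the core tile; it is off by
#' default.
#'
#' @param raster Numeric or integer matrix (an intensity image, or a label
#'   raster for the identity stand-in).
#' @param segmenter A callable satisfying the segmenter contract (see
#'   [segmenter_identity()]).
#' @param legend A [class_legend()] the outputs must respect.
#' @param grid Optional tile grid from [plan_grid()]; planned from the raster
#'   extent with `tile_size` when absent.
#' @param tile_size Tile side used when `grid` is `NULL`.
#' @param mpp Microns per pixel recorded on the stitched mask.
#' @param overlap_px Context margin read around each tile (cropped away after
#'   segmentation).
#' @param slide_id Optional slide identifier for the stitched mask.
#' @return A [tissue_mask()] with exactly the input extent.
#' @export
run_inference <- function(raster, segmenter, legend, grid = NULL,
                          tile_size = 512, mpp = 1.0, overlap_px = 0,
                          slide_id = NULL) {
  stopifnot(is.matrix(raster), is.function(segmenter))
  h <- nrow(raster); w <- ncol(raster)
  if (is.null(grid)) grid <- plan_grid(h, w, tile_size)
  out <- matrix(NA_integer_, h, w)
  for (i in seq_len(nrow(grid))) {
    r0 <- grid$row_off[i]; c0 <- grid$col_off[i]
    th <- grid$height[i]; tw <- grid$width[i]
    rr <- max(1L, r0 + 1L - overlap_px):min(h, r0 + th + overlap_px)
    cc <- max(1L, c0 + 1L - overlap_px):min(w, c0 + tw + overlap_px)
    pred <- segmenter(raster[rr, cc, drop = FALSE])
    if (!is.matrix(pred) ||
        !identical(dim(pred), c(length(rr), length(cc)))) {
      abort(sprintf(
        "segmenter broke its contract on tile %d (row_off %d, col_off %d): expected %dx%d output",
        grid$tile_id[i], r0, c0, length(rr), length(cc)),
        class = "tissuemaps_contract_error")
    }
    core_r <- (r0 + 1L):(r0 + th) - rr[1] + 1L
    core_c <- (c0 + 1L):(c0 + tw) - cc[1] + 1L
    out[(r0 + 1L):(r0 + th), (c0 + 1L):(c0 + tw)] <-
      as.integer(pred[core_r, core_c, drop = FALSE])
  }
  tissue_mask(out, legend, mpp = mpp, slide_id = slide_id)
}

#' Rescale a label raster to a target resolution
#'
#' Nearest-neighbor resampling only: label rasters carry class identity, and
#' any interpolation would fabricate classes. The scale factor is
#' `source_mpp / target_mpp`; each output pixel takes the label of the source
#' pixel its center falls on.
#'
#' @param x A [tissue_mask()] or a label matrix.
#' @param source_mpp,target_mpp Microns per pixel before/after (> 0). For a
#'   `tissue_mask`, `source_mpp` defaults to the mask's own `mpp`.
#' @return Same type as `x`, at the target resolution.
#' @export
rescale_to_target_mpp <- function(x, target_mpp, source_mpp = NULL) {
  UseMethod("rescale_to_target_mpp")
}

#' @export
rescale_to_target_mpp.matrix <- function(x, target_mpp, source_mpp = NULL) {
  if (is.null(source_mpp)) {
    abort("source_mpp is required for a bare matrix",
          class = "tissuemaps_value_error")
  }
  check_mpp(source_mpp); check_mpp(target_mpp)
  if (source_mpp == target_mpp) return(x)
  scale <- source_mpp / target_mpp
  out_h <- max(1L, as.integer(round(nrow(x) * scale)))
  out_w <- max(1L, as.integer(round(ncol(x) * scale)))
  src_r <- pmin(nrow(x), pmax(1L, floor((seq_len(out_h) - 0.5) / scale) + 1L))
  src_c <- pmin(ncol(x), pmax(1L, floor((seq_len(out_w) - 0.5) / scale) + 1L))
  x[src_r, src_c, drop = FALSE]
}

#' @export
rescale_to_target_mpp.tissue_mask <- function(x, target_mpp, source_mpp = NULL) {
  source_mpp <- source_mpp %||% x$mpp
  labels <- rescale_to_target_mpp(x$labels, target_mpp, source_mpp)
  tissue_mask(labels, x$legend, mpp = target_mpp, slide_id = x$slide_id)
}

check_mpp <- function(mpp) {
  if (!is.numeric(mpp) || length(mpp) != 1 || is.na(mpp) || mpp <= 0) {
    abort("mpp must be a positive number", class = "tissuemaps_value_error")
  }
  invisible(mpp)
}
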