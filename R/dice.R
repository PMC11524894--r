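#' Per-class Dice evaluation of a predicted mask
#'
#' Computes, for every legend class `c`, the Dice overlap
#' `2 |T_c ∩ P_c| / (|T_c| + |P_c|)` between the ground-truth and predicted
#' pixel sets, optionally restricted to an annotated region so that pixels
#' outside the annotation never influence any score (the validation protocol
#' for segmentation masks: only the intersection of annotated and predicted
#' regions is compared, and 1.0 is ideal agreement).
#'
#' A class absent from both masks (inside the region) has no defined Dice and
#' is reported as `NA`, not 0, and is excluded from the macro average. The
#' `pooled` summary is the micro average `2 Σ|T_c ∩ P_c| / Σ(|T_c| + |P_c|)`
#' over all classes, an alternative reading of an "overall" score.
#'
#' @param truth,pred [tissue_mask()]s with identical dimensions and legends.
#' @param region Optional logical matrix marking annotated pixels.
#' @return A `dice_report`: the per-class tibble (`class_id`, `class_name`,
#'   `dice`, `support_truth_px`, `support_pred_px`) with macro/pooled
#'   summaries available through [glance()].
#' @examples
#' m <- tissue_mask(matrix(c(1L, 1L, 2L, 0L), 2, 2), default_legend())
#' glance(dice_scores(m, m))$macro_dice   # identical masks score 1
#' @export
dice_scores <- function(truth, pred, region = NULL) {
  stopifnot(inherits(truth, "tissue_mask"), inherits(pred, "tissue_mask"))
  if (!identical(dim(truth$labels), dim(pred$labels))) {
    abort("truth and pred have different dimensions",
          class = "tissuemaps_shape_error")
  }
  if (!identical(truth$legend$class_name, pred$legend$class_name)) {
    abort("truth and pred use different legends",
          class = "tissuemaps_shape_error")
  }
  t_lab <- truth$labels
  p_lab <- pred$labels
  if (!is.null(region)) {
    if (!identical(dim(region), dim(t_lab))) {
      abort("region has different dimensions than the masks",
            class = "tissuemaps_shape_error")
    }
    keep <- as.logical(region)
    t_lab <- t_lab[keep]
    p_lab <- p_lab[keep]
  }
  legend <- truth$legend
  per_class <- map(legend$class_id, function(id) {
    t_sup <- sum(t_lab == id)
    p_sup <- sum(p_lab == id)
    inter <- sum(t_lab == id & p_lab == id)
    tibble(class_id = id,
           support_truth_px = t_sup, support_pred_px = p_sup,
           intersection_px = inter,
           dice = if (t_sup + p_sup > 0) 2 * inter / (t_sup + p_sup) else NA_real_)
  })
  per_class <- bind_rows(per_class)
  per_class <- mutate(per_class,
                      class_name = legend$class_name[match(.data$class_id,
                                                           legend$class_id)],
                      .after = "class_id")
  structure(per_class, class = c("dice_report", class(tibble())))
}

#' @export
tidy.dice_report <- function(x, ...) {
  as_tibble(x)[, c("class_id", "class_name", "dice",
                   "support_truth_px", "support_pred_px")]
}

#' @export
glance.dice_report <- function(x, ...) {
  defined <- !is.na(x$dice)
  denom <- sum(x$support_truth_px + x$support_pred_px)
  tibble(
    macro_dice = if (any(defined)) mean(x$dice[defined]) else NA_real_,
    pooled_dice = if (denom > 0) 2 * sum(x$intersection_px) / denom else NA_real_,
    n_classes_scored = sum(defined)
  )
}

#' @export
autoplot.dice_report <- function(object, ...) {
  df <- filter(tidy(object), !is.na(.data$dice))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class_name, .data$dice), y = .data$dice)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Dice", title = "Per-class segmentation Dice") +
    ggplot2::theme_minimal()
}

#' Write a Dice report to CSV
#'
#' @param report A `dice_report` from [dice_scores()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dice_report <- function(report, path) {
  readr::write_csv(tidy(report), path)
  invisible(path)
}
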