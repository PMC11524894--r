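#' Optimal-cutpoint dichotomization of a prognostic parameter
#'
#' Scans candidate cutoffs on a quantile grid (percentiles 10-90 in steps of
#' 2.5 by default) and returns the cutoff whose low/high split maximizes the
#' two-group log-rank statistic — the stratification with best prognostic
#' significance — subject to a minimum group size (10% of the cohort by
#' default, at least 2). The full per-candidate statistic trace is kept for
#' audit; no multiplicity correction is applied across the grid, so users
#' who want corrected inference can apply one to the trace. The same cutoff
#' is intended to be reused across survival endpoints.
#'
#' Cases with `NA` parameter values (e.g., undefined T/NR when a tumor has
#' no necrosis) are excluded from the scan.
#'
#' @param data Data frame with one row per case.
#' @param values,time,event Columns (tidy-eval): parameter value, follow-up
#'   time, event indicator.
#' @param probs Quantile grid of candidate cutoffs.
#' @param min_group_frac Minimum fraction of the cohort in each group.
#' @return A `cutoff_result`; [glance()] gives the optimum,
#'   [tidy()] the full trace (`cutoff`, `statistic`, `p_value`, `n_low`,
#'   `n_high`, `admissible`).
#' @examples
#' # two clusters with different hazards: the chosen cutoff falls between them
#' @export
find_optimal_cutoff <- function(data, values, time, event,
                                probs = seq(0.10, 0.90, by = 0.025),
                                min_group_frac = 0.10) {
  parameter <- as_name(enquo(values))
  v <- dplyr::pull(data, {{ values }})
  tm <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  keep <- !is.na(v)
  v <- v[keep]; tm <- tm[keep]; ev <- ev[keep]
  check_records(tm, ev)
  n <- length(v)
  if (n < 4 || sum(ev) == 0) {
    abort("too few cases or no events for stratification",
          class = "tissuemaps_stratification_error")
  }
  if (length(unique(v)) == 1) {
    abort("all parameter values identical; cohort cannot be stratified",
          class = "tissuemaps_stratification_error")
  }
  min_size <- max(2L, ceiling(min_group_frac * n))
  candidates <- sort(unique(unname(quantile(v, probs, type = 7))))
  trace <- purrr::map(candidates, function(cand) {
    hi <- v > cand
    n_hi <- sum(hi)
    row <- tibble(cutoff = cand, n_low = n - n_hi, n_high = n_hi,
                  statistic = NA_real_, p_value = NA_real_,
                  admissible = n_hi >= min_size & (n - n_hi) >= min_size)
    if (!row$admissible) return(row)
    res <- logrank_chisq(tm, ev, hi)
    row$statistic <- res$chisq
    row$p_value <- pchisq(res$chisq, 1, lower.tail = FALSE)
    row
  }) |> bind_rows()
  if (!any(trace$admissible)) {
    abort("no candidate cutoff satisfies the minimum group-size constraint",
          class = "tissuemaps_stratification_error")
  }
  adm <- trace[trace$admissible, ]
  best <- adm[which.max(adm$statistic), ]  # first maximum: smallest cutoff
  structure(
    list(parameter = parameter, cutoff = best$cutoff,
         statistic = best$statistic, p_value = best$p_value,
         n_low = best$n_low, n_high = best$n_high,
         n_used = n, min_group_size = min_size, trace = trace),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> %s: cutoff %.6g (log-rank chi2 %.3f, p %.3g; low/high %d/%d)\n",
    x$parameter, x$cutoff, x$statistic, x$p_value, x$n_low, x$n_high))
  invisible(x)
}

#' @export
tidy.cutoff_result <- function(x, ...) x$trace

#' @export
glance.cutoff_result <- function(x, ...) {
  tibble(parameter = x$parameter, cutoff = x$cutoff, statistic = x$statistic,
         p_value = x$p_value, n_low = x$n_low, n_high = x$n_high,
         n_used = x$n_used)
}

#' @export
autoplot.cutoff_result <- function(object, ...) {
  df <- filter(tidy(object), .data$admissible)
  ggplot2::ggplot(df, ggplot2::aes(.data$cutoff, .data$statistic)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = object$parameter, y = "Log-rank chi-square",
                  title = "Optimal-cutpoint scan") +
    ggplot2::theme_minimal()
}
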