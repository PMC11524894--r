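#' Kaplan-Meier product-limit estimate
#'
#' Native product-limit estimator used by the stratification layer. The
#' survival curve is right-continuous, non-increasing, starts at 1.0 and
#' drops only at event times.
#'
#' @param data A data frame of survival records.
#' @param time,event Columns (tidy-eval) holding follow-up time (> 0, months
#'   by convention) and event indicator (0 censored / 1 event).
#' @param group Optional column splitting the cohort into strata.
#' @return A `km_fit`: a tibble with one row per distinct time per stratum
#'   (`group`, `time`, `n_risk`, `n_event`, `n_censor`, `survival`).
#'   `km_survival()` evaluates a stratum's step function.
#' @examples
#' d <- tibble::tibble(time = c(5, 8, 12), event = c(1, 0, 1))
#' km_estimate(d, time, event)
#' @export
km_estimate <- function(data, time, event, group = NULL) {
  time <- dplyr::pull(data, {{ time }})
  event <- dplyr::pull(data, {{ event }})
  grp_quo <- enquo(group)
  grp <- if (rlang::quo_is_null(grp_quo)) {
    rep("all", length(time))
  } else {
    as.character(dplyr::pull(data, !!grp_quo))
  }
  check_records(time, event)
  out <- bind_rows(lapply(split(seq_along(time), grp), function(i) {
    km_one(time[i], event[i])
  }), .id = "group")
  structure(out, class = c("km_fit", class(tibble())))
}

km_one <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  tibble(time = ut, n_risk = n_risk, n_event = n_event, n_censor = n_censor,
         survival = cumprod(1 - n_event / n_risk))
}

check_records <- function(time, event) {
  if (length(time) == 0) {
    abort("no survival records", class = "tissuemaps_value_error")
  }
  if (any(is.na(time)) || any(time <= 0)) {
    abort("times must be positive and non-missing",
          class = "tissuemaps_value_error")
  }
  if (!all(event %in% c(0, 1))) {
    abort("event must be 0/1", class = "tissuemaps_value_error")
  }
  invisible(NULL)
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param fit A `km_fit`.
#' @param at Times at which to evaluate survival.
#' @param group Stratum name (defaults to the first).
#' @return Numeric survival probabilities.
#' @export
km_survival <- function(fit, at, group = NULL) {
  group <- group %||% fit$group[1]
  f <- fit[fit$group == group, ]
  stats::stepfun(f$time, c(1, f$survival), right = FALSE)(at)
}

#' @export
autoplot.km_fit <- function(object, ...) {
  df <- bind_rows(lapply(split(object, object$group), function(f) {
    tibble(group = f$group[1], time = c(0, f$time),
           survival = c(1, f$survival))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Native log-rank test with the standard pooled risk-table (hypergeometric
#' variance) handling of tied event times. Implemented natively because the
#' optimal-cutpoint scan evaluates it on a whole grid of candidate splits.
#'
#' @param data A data frame of survival records.
#' @param time,event,group Columns (tidy-eval); `group` must take exactly two
#'   values.
#' @return A tibble: `statistic` (chi-square, 1 df), `p_value`, `n_1`, `n_2`,
#'   `observed_1`, `expected_1`.
#' @export
logrank_test <- function(data, time, event, group) {
  time <- dplyr::pull(data, {{ time }})
  event <- dplyr::pull(data, {{ event }})
  grp <- as.character(dplyr::pull(data, {{ group }}))
  check_records(time, event)
  lv <- sort(unique(grp))
  if (length(lv) != 2) {
    abort("log-rank test needs exactly two groups",
          class = "tissuemaps_test_error")
  }
  if (sum(event) == 0) {
    abort("log-rank test needs at least one event",
          class = "tissuemaps_test_error")
  }
  res <- logrank_chisq(time, event, grp == lv[2])
  tibble(statistic = res$chisq, p_value = pchisq(res$chisq, 1, lower.tail = FALSE),
         n_1 = sum(grp == lv[1]), n_2 = sum(grp == lv[2]),
         observed_1 = res$o1, expected_1 = res$e1)
}

# core O-E/V computation shared with the cutoff scan; g2 is logical
logrank_chisq <- function(time, event, g2) {
  et <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & !g2)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & !g2)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chisq = chisq, o1 = o1, e1 = e1, v = v)
}

#' Cox proportional-hazards fit with pT/pN covariates
#'
#' Thin wrapper over [survival::coxph()] (partial likelihood, Efron tie
#' handling) returning tidy hazard ratios. The multivariate models of the
#' prognostic layer always contain one prognostic parameter plus the pT and
#' pN category covariates; categorical covariates are dummy-encoded against
#' their first level.
#'
#' @param data Data frame of records.
#' @param time,event Column names (strings) of follow-up and event.
#' @param covariates Character vector of covariate columns.
#' @return A `cox_result`; [tidy()] gives per-term `hr`, `ci_low`, `ci_high`
#'   (95%), `p_value`; [glance()] gives model-level fit measures.
#' @export
cox_fit <- function(data, time, event, covariates) {
  stopifnot(length(covariates) >= 1)
  for (cv in covariates) {
    vals <- data[[cv]]
    if (length(unique(vals[!is.na(vals)])) < 2) {
      abort(paste0("covariate is constant across the cohort: ", cv),
            class = "tissuemaps_fit_error")
    }
  }
  keep <- stats::complete.cases(data[, c(time, event, covariates)])
  d <- data[keep, ]
  if (sum(d[[event]]) < length(covariates)) {
    abort("fewer events than covariates", class = "tissuemaps_fit_error")
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = d, ties = "efron"),
    error = function(e) abort(paste0("Cox fit failed: ", conditionMessage(e)),
                              class = "tissuemaps_fit_error"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        abort(paste0("Cox fit did not converge: ", conditionMessage(w)),
              class = "tissuemaps_fit_error")
      }
      suppressWarnings(survival::coxph(fml, data = d, ties = "efron"))
    }
  )
  s <- summary(fit)
  res <- tibble(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"])
  )
  structure(list(fit = fit, terms = res, endpoint = c(time = time, event = event),
                 covariates = covariates, n = s$n, n_events = s$nevent),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s/%s, n = %d, events = %d\n",
              x$endpoint["time"], x$endpoint["event"], x$n, x$n_events))
  print(x$terms)
  invisible(x)
}

#' @export
tidy.cox_result <- function(x, ...) x$terms

#' @export
glance.cox_result <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         concordance = unname(summary(x$fit)$concordance["C"]),
         logtest_p = unname(summary(x$fit)$logtest["pvalue"]))
}

#' @export
autoplot.cox_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$hr, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
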