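test_that("Kaplan-Meier handles single-record and all-censored cohorts", {
  one <- tibble::tibble(time = 5, event = 1)
  fit <- km_estimate(one, time, event)
  expect_equal(km_survival(fit, c(1, 4.99, 5, 10)), c(1, 1, 0, 0))

  cens <- tibble::tibble(time = c(3, 6, 9), event = 0)
  fit2 <- km_estimate(cens, time, event)
  expect_true(all(km_survival(fit2, c(1, 5, 20)) == 1))

  expect_error(km_estimate(tibble::tibble(time = numeric(), event = integer()),
                           time, event),
               class = "tissuemaps_value_error")
})

test_that("product-limit values match a hand-computed toy cohort", {
  # times 2(e) 3(c) 5(e) 7(e): S = 3/4, then 3/4 * 1/2, then 0
  d <- tibble::tibble(time = c(2, 3, 5, 7), event = c(1, 0, 1, 1))
  fit <- km_estimate(d, time, event)
  expect_equal(km_survival(fit, c(2, 3, 5, 7)), c(0.75, 0.75, 0.375, 0))

  # 10-record cohort against the product-limit formula worked by hand
  d10 <- tibble::tibble(
    time = c(1, 2, 2, 3, 4, 5, 6, 6, 8, 9),
    event = c(1, 1, 0, 1, 0, 1, 1, 1, 0, 1))
  fit10 <- km_estimate(d10, time, event)
  s <- fit10$survival[fit10$n_event > 0]
  expect_equal(s, c(9 / 10,
                    9 / 10 * 8 / 9,
                    9 / 10 * 8 / 9 * 6 / 7,
                    9 / 10 * 8 / 9 * 6 / 7 * 4 / 5,
                    9 / 10 * 8 / 9 * 6 / 7 * 4 / 5 * 3 / 4 * 2 / 3,
                    0))
})

test_that("the KM curve is non-increasing and order-invariant", {
  set.seed(12)
  for (i in 1:10) {
    d <- tibble::tibble(time = round(rexp(40, 0.1) + 0.5, 1),
                        event = rbinom(40, 1, 0.6))
    fit <- km_estimate(d, time, event)
    expect_true(all(diff(fit$survival) <= 1e-12))
    shuf <- d[sample(nrow(d)), ]
    expect_equal(km_estimate(shuf, time, event), fit)
    # agrees with the standard estimator
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    expect_equal(km_survival(fit, sf$time), sf$surv, tolerance = 1e-12)
  }
})

test_that("log-rank is zero for identical groups and symmetric in labels", {
  d <- tibble::tibble(time = c(2, 4, 6, 8), event = c(1, 0, 1, 1))
  both <- dplyr::bind_rows(dplyr::mutate(d, g = "a"),
                           dplyr::mutate(d, g = "b"))
  res <- logrank_test(both, time, event, g)
  expect_equal(res$statistic, 0)

  set.seed(8)
  d2 <- tibble::tibble(time = rexp(50, 0.1) + 0.1, event = rbinom(50, 1, 0.7),
                       g = sample(c("x", "y"), 50, TRUE))
  d2_flip <- dplyr::mutate(d2, g = ifelse(g == "x", "y", "x"))
  expect_equal(logrank_test(d2, time, event, g)$statistic,
               logrank_test(d2_flip, time, event, g)$statistic)
})

test_that("log-rank matches the explicit risk-table oracle and survdiff", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    d <- tibble::tibble(
      time = round(rexp(n, 0.08), 2) + 0.01,
      event = rbinom(n, 1, 0.7),
      g = sample(c("a", "b"), n, TRUE, prob = c(0.5, 0.5)))
    if (length(unique(d$g)) < 2 || sum(d$event) == 0) next
    mine <- logrank_test(d, time, event, g)
    expect_equal(mine$statistic, brute_logrank(d$time, d$event, d$g))
    ref <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  }
  expect_error(logrank_test(tibble::tibble(time = c(1, 2), event = c(0, 0),
                                           g = c("a", "b")),
                            time, event, g),
               class = "tissuemaps_test_error")
  expect_error(logrank_test(tibble::tibble(time = 1, event = 1, g = "a"),
                            time, event, g),
               class = "tissuemaps_test_error")
})

test_that("permuted labels give approximately uniform log-rank p-values", {
  set.seed(5)
  base <- tibble::tibble(time = rexp(60, 0.05) + 0.1,
                         event = rbinom(60, 1, 0.7))
  p <- replicate(200, {
    g <- sample(rep(c("a", "b"), 30))
    logrank_test(dplyr::mutate(base, g = g), time, event, g)$p_value
  })
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.60)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("Cox recovers a known hazard ratio and rejects constant covariates", {
  set.seed(14)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.02 * 2^x)
  t_c <- rexp(n, 0.008)
  d <- tibble::tibble(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
                      x = x)
  fit <- cox_fit(d, "time", "event", "x")
  hr <- tidy(fit)$hr
  expect_gt(hr, 1.6); expect_lt(hr, 2.5)
  expect_true(tidy(fit)$ci_low <= hr && hr <= tidy(fit)$ci_high)

  d$z <- 1
  expect_error(cox_fit(d, "time", "event", "z"),
               class = "tissuemaps_fit_error")
})

test_that("a null covariate's CI covers 1 in most simulated cohorts", {
  covered <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 300
    x1 <- rbinom(n, 1, 0.5)          # true HR 2
    x2 <- rnorm(n)                   # true HR 1
    t_ev <- rexp(n, 0.02 * 2^x1)
    t_c <- rexp(n, 0.008)
    d <- tibble::tibble(time = pmin(t_ev, t_c),
                        event = as.integer(t_ev <= t_c), x1 = x1, x2 = x2)
    td <- tidy(cox_fit(d, "time", "event", c("x1", "x2")))
    row <- td[td$term == "x2", ]
    if (row$ci_low <= 1 && 1 <= row$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 17)  # nominal 95% coverage over 20 seeds
})

test_that("multivariate fits with categorical pT/pN dummy-encode covariates", {
  spec <- synth_spec(n = 150, hr_tls = 0.5, hr_necr = 2)
  d <- generate_cohort(spec, seed = 77)
  d$tls_group <- as.character(dichotomize(d$tls_td, stats::median(d$tls_td)))
  fit <- cox_fit(d, "time_os", "event_os", c("tls_group", "pT", "pN"))
  td <- tidy(fit)
  expect_true(any(grepl("^pT", td$term)) && any(grepl("^pN", td$term)))
  # reference levels absorbed: pT contributes 3 dummies, pN 2
  expect_equal(sum(grepl("^pT", td$term)), 3)
  expect_equal(sum(grepl("^pN", td$term)), 2)
})
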