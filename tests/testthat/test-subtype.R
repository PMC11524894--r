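# builds a main/subtype mask pair with the requested LUAD/LUSC pixel counts
# inside the tumor support, plus optional mucin/stroma context
subtype_pair <- function(n_luad, n_lusc, n_mucin = 0, n_stroma = 0,
                         side = 32) {
  lg <- default_legend(); sg <- subtype_legend()
  total <- n_luad + n_lusc + n_mucin + n_stroma
  stopifnot(total <= side * side)
  main <- matrix(legend_id_t(lg, "LUNG_BENIGN"), side, side)
  sub <- matrix(legend_id_t(sg, "BACK"), side, side)
  idx <- seq_len(total)
  main[idx[seq_len(n_luad + n_lusc)]] <- legend_id_t(lg, "TUMOR")
  if (n_mucin > 0) main[idx[n_luad + n_lusc + seq_len(n_mucin)]] <-
      legend_id_t(lg, "MUCIN")
  if (n_stroma > 0) main[idx[n_luad + n_lusc + n_mucin + seq_len(n_stroma)]] <-
      legend_id_t(lg, "TU_STROMA")
  sub[idx[seq_len(n_luad)]] <- legend_id_t(sg, "TUMOR_LUAD")
  sub[idx[n_luad + seq_len(n_lusc)]] <- legend_id_t(sg, "TUMOR_LUSC")
  if (n_mucin > 0) sub[idx[n_luad + n_lusc + seq_len(n_mucin)]] <-
      legend_id_t(sg, "MUCIN")
  if (n_stroma > 0) sub[idx[n_luad + n_lusc + n_mucin + seq_len(n_stroma)]] <-
      legend_id_t(sg, "TU_STROMA")
  list(main = tissue_mask(main, lg, slide_id = "s1"),
       sub = tissue_mask(sub, sg))
}

test_that("tumor support is the main mask's TUMOR pixels exactly", {
  p <- subtype_pair(20, 10)
  sup <- restrict_to_tumor(p$main, p$sub)
  expect_equal(sup, p$main$labels == legend_id_t(default_legend(), "TUMOR"))
  lg <- default_legend()
  none <- tissue_mask(matrix(legend_id_t(lg, "BACK"), 4, 4), lg)
  expect_false(any(restrict_to_tumor(none)))
  all_t <- tissue_mask(matrix(legend_id_t(lg, "TUMOR"), 4, 4), lg)
  expect_true(all(restrict_to_tumor(all_t)))
  expect_error(restrict_to_tumor(p$main, rand_mask(4, 4, seed = 1)),
               class = "tissuemaps_shape_error")
})

test_that("area percentages drive the slide call and borderline flag", {
  p <- subtype_pair(70, 30)
  call <- classify_slide(p$main, p$sub)
  expect_equal(call$call, "LUAD")
  expect_equal(call$pct_luad, 70)
  expect_equal(call$pct_lusc, 30)
  expect_false(call$borderline)

  p2 <- subtype_pair(55, 45)
  call2 <- classify_slide(p2$main, p2$sub)
  expect_equal(call2$call, "LUAD")
  expect_true(call2$borderline)

  p3 <- subtype_pair(30, 70)
  expect_equal(classify_slide(p3$main, p3$sub)$call, "LUSC")
})

test_that("an exact tie calls LUAD with a borderline warning", {
  p <- subtype_pair(50, 50)
  expect_warning(call <- classify_slide(p$main, p$sub), regexp = "50/50")
  expect_equal(call$call, "LUAD")
  expect_true(call$borderline)
  expect_equal(call$pct_luad + call$pct_lusc, 100)
})

test_that("a slide without evaluable tumor yields an explicit no-tumor call", {
  p <- subtype_pair(0, 0, n_stroma = 10)
  call <- classify_slide(p$main, p$sub)
  expect_equal(call$call, "no_tumor")
  expect_true(is.na(call$pct_luad))
})

test_that("mucin fraction follows area mucin / (mucin + tumor + stroma)", {
  p <- subtype_pair(40, 30, n_mucin = 10, n_stroma = 20)
  expect_equal(mucin_fraction(p$sub, p$main), 10)
  p0 <- subtype_pair(40, 30, n_mucin = 0, n_stroma = 20)
  expect_equal(mucin_fraction(p0$sub, p0$main), 0)
  empty <- subtype_pair(0, 0)
  expect_true(is.na(mucin_fraction(empty$sub, empty$main)))
})

test_that("subtype labels outside the tumor support never change the call", {
  p <- subtype_pair(60, 40)
  base <- classify_slide(p$main, p$sub)
  tampered <- p$sub
  outside <- !restrict_to_tumor(p$main)
  # also keep clear of the mucin denominator region (main tumor region)
  region <- matrix(p$main$labels %in%
    legend_id_t(default_legend(), c("TUMOR", "TU_STROMA", "NECROSIS", "MUCIN")),
    nrow(p$main$labels))
  pick <- which(outside & !region)
  tampered$labels[pick] <-
    legend_id_t(subtype_legend(), "TUMOR_LUSC")
  expect_equal(classify_slide(p$main, tampered), base)
})

test_that("case aggregation pools raw counts and is order-invariant", {
  p1 <- subtype_pair(900, 100)           # 90/10 on 1000 tumor px
  p2 <- subtype_pair(4, 6)               # 40/60 on 10 tumor px
  c1 <- classify_slide(p1$main, p1$sub)
  c2 <- classify_slide(p2$main, p2$sub)
  case_ab <- aggregate_case(dplyr::bind_rows(c1, c2), case_id = "K1")
  case_ba <- aggregate_case(dplyr::bind_rows(c2, c1), case_id = "K1")
  expect_equal(case_ab, case_ba)
  expect_equal(case_ab$call, "LUAD")
  expect_equal(case_ab$pct_luad, 100 * 904 / 1010)
  expect_equal(case_ab$level, "case")

  solo <- aggregate_case(c1, case_id = "K2")
  expect_equal(solo$pct_luad, c1$pct_luad)
  expect_equal(solo$call, c1$call)

  t1 <- subtype_pair(25, 25); t2 <- subtype_pair(10, 10)
  ct <- suppressWarnings(
    aggregate_case(dplyr::bind_rows(
      suppressWarnings(classify_slide(t1$main, t1$sub)),
      suppressWarnings(classify_slide(t2$main, t2$sub))), case_id = "K3"))
  expect_true(ct$borderline)
  expect_equal(ct$pct_luad, 50)

  n1 <- subtype_pair(0, 0); n2 <- subtype_pair(0, 0)
  cn <- aggregate_case(dplyr::bind_rows(
    classify_slide(n1$main, n1$sub), classify_slide(n2$main, n2$sub)),
    case_id = "K4")
  expect_equal(cn$call, "no_tumor")
})

test_that("pct_luad and pct_lusc always sum to 100 on evaluable slides", {
  set.seed(21)
  for (i in 1:10) {
    p <- subtype_pair(sample(1:200, 1), sample(1:200, 1))
    call <- suppressWarnings(classify_slide(p$main, p$sub))
    expect_equal(call$pct_luad + call$pct_lusc, 100)
  }
})
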