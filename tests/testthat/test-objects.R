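test_that("connected components of a class are extracted without filtering", {
  lg <- default_legend()
  labels <- matrix(legend_id_t(lg, "LUNG_BENIGN"), 16, 16)
  labels[2:3, 2:3] <- legend_id_t(lg, "TLS")          # 4 px... make 5
  labels[4, 2] <- legend_id_t(lg, "TLS")              # 5 px blob
  labels[10:12, 10:11] <- legend_id_t(lg, "TLS")      # 6 px... make 7
  labels[13, 10] <- legend_id_t(lg, "TLS")            # 7 px blob
  m <- tissue_mask(labels, lg, mpp = 2)
  obj <- extract_objects(m, "TLS")
  expect_equal(nrow(obj), 2)
  expect_setequal(obj$area_px, c(5, 7))
  expect_equal(obj$area_um2, obj$area_px * 4)

  labels1 <- matrix(legend_id_t(lg, "TUMOR"), 8, 8)
  labels1[5, 5] <- legend_id_t(lg, "NECROSIS")
  one <- extract_objects(tissue_mask(labels1, lg), "NECROSIS")
  expect_equal(one$area_px, 1)   # single-pixel objects are kept

  expect_equal(nrow(extract_objects(m, "CARTIL")), 0)
  expect_error(extract_objects(m, "NOPE"), class = "tissuemaps_legend_error")
})

test_that("connectivity 8 joins diagonals and connectivity 4 does not", {
  lg <- default_legend()
  labels <- matrix(legend_id_t(lg, "LUNG_BENIGN"), 6, 6)
  labels[cbind(c(2, 3), c(2, 3))] <- legend_id_t(lg, "TLS")
  m <- tissue_mask(labels, lg)
  expect_equal(nrow(extract_objects(m, "TLS", connectivity = 8)), 1)
  expect_equal(nrow(extract_objects(m, "TLS", connectivity = 4)), 2)
})

test_that("labeling matches the flood-fill oracle on random rasters", {
  set.seed(17)
  for (i in 1:20) {
    bin <- matrix(runif(48 * 48) < runif(1, 0.2, 0.6), 48)
    for (conn in c(8L, 4L)) {
      mine <- tissuemaps:::cc_label(bin, conn)
      oracle <- flood_label(bin, conn)
      expect_equal(max(mine), max(oracle))
      # same partition: labels must be a relabeling of each other
      expect_equal(length(unique(paste(mine[bin], oracle[bin]))),
                   max(mine))
    }
  }
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  set.seed(23)
  bin <- matrix(runif(64 * 64) < 0.4, 64)
  mine <- tissuemaps:::cc_label(bin, 4L)
  ref <- EBImage::bwlabel(matrix(as.numeric(bin), 64))
  expect_equal(max(mine), max(ref))
})

test_that("objects qualify by adjacency and distance to the tumor region", {
  lg <- default_legend()
  labels <- matrix(legend_id_t(lg, "LUNG_BENIGN"), 60, 120)
  labels[20:40, 10:40] <- legend_id_t(lg, "TU_STROMA")
  labels[25:35, 15:30] <- legend_id_t(lg, "TUMOR")
  labels[28:30, 20:22] <- legend_id_t(lg, "TLS")       # inside tumor stroma
  labels[28:30, 51:53] <- legend_id_t(lg, "TLS")       # 10 px from edge
  labels[28:30, 101:103] <- legend_id_t(lg, "TLS")     # 60 px away
  m <- tissue_mask(labels, lg, mpp = 1)
  obj <- qualify_objects(extract_objects(m, "TLS"), m,
                         peritumoral_dist_um = 25)
  obj <- obj[order(purrr::map_dbl(obj$pixels, min)), ]
  expect_equal(obj$qualification,
               c("intratumoral", "peritumoral", "non_tumor_associated"))
  # distance from col 51 to tumor-region edge col 40 is 11 px
  expect_equal(obj$min_dist_um[2], 11)

  # with a 250 um threshold the far blob becomes peritumoral too
  obj250 <- qualify_objects(extract_objects(m, "TLS"), m,
                            peritumoral_dist_um = 250)
  expect_equal(sum(obj250$qualification == "peritumoral"), 2)
})

test_that("qualification matches the exhaustive pairwise-distance oracle", {
  lg <- default_legend()
  set.seed(31)
  for (i in 1:20) {
    labels <- build_layout(48, tumor_rad = sample(6:14, 1), seed = i)
    # sprinkle TLS and NECROSIS discs at random positions
    for (k in 1:4) {
      cls <- sample(c("TLS", "NECROSIS"), 1)
      px <- disc_pixels(48, 48, sample(4:45, 1), sample(4:45, 1),
                        sample(1:3, 1))
      px <- px[labels[px] != legend_id_t(lg, "TUMOR")]
      if (length(px)) labels[px] <- legend_id_t(lg, cls)
    }
    m <- tissue_mask(labels, lg, mpp = runif(1, 0.5, 2))
    thr <- sample(c(5, 12, 25), 1)
    for (cls in c("TLS", "NECROSIS")) {
      obj <- extract_objects(m, cls)
      if (nrow(obj) == 0) next
      got <- qualify_objects(obj, m, peritumoral_dist_um = thr)
      expect_equal(got$qualification, brute_qualify(obj, m, thr))
    }
  }
})

test_that("necrosis isolated in benign lung is not tumor-associated", {
  lg <- default_legend()
  labels <- build_layout(64, tumor_rad = 10)
  labels[disc_pixels(64, 64, 58, 58, 3)] <- legend_id_t(lg, "NECROSIS")
  m <- tissue_mask(labels, lg)
  obj <- qualify_objects(extract_objects(m, "NECROSIS"), m,
                         peritumoral_dist_um = 10)
  expect_equal(obj$qualification, "non_tumor_associated")
  # and it contributes nothing to the density
  expect_equal(prognostic_scores(m, peritumoral_dist_um = 10)$necr_td, 0)
})

test_that("a mask with no tumor region leaves all objects unassociated", {
  lg <- default_legend()
  labels <- matrix(legend_id_t(lg, "LUNG_BENIGN"), 20, 20)
  labels[5:6, 5:6] <- legend_id_t(lg, "TLS")
  m <- tissue_mask(labels, lg)
  obj <- qualify_objects(extract_objects(m, "TLS"), m)
  expect_equal(obj$qualification, "non_tumor_associated")
  expect_equal(obj$min_dist_um, Inf)
})
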