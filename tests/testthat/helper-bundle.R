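# build a small on-disk cohort: masks with varying planted densities, a
# manifest, matching subtype masks derived deterministically from the main
# masks, and a clinical table
build_bundle <- function(dir, n_cases = 6, canvas = 96, seed = 1,
                         with_subtype = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  rows <- list()
  lg <- default_legend(); sg <- subtype_legend()
  for (i in seq_len(n_cases)) {
    spec <- synth_spec(canvas_px = canvas, peritumoral_dist_um = 15,
                       radius_px = c(2, 5),
                       f_tls = runif(1, 0.01, 0.06),
                       f_necrosis = runif(1, 0.02, 0.12),
                       f_mucin = 0.005,
                       tls_mix = c(intratumoral = 0.6, peritumoral = 0.4,
                                   distant = 0))
    g <- generate_mask(spec, seed = seed * 1000 + i)
    mask_path <- file.path(dir, sprintf("mask_%02d.png", i))
    write_mask(g$mask, mask_path)
    sub_path <- NA_character_
    if (with_subtype) {
      main <- g$mask$labels
      sub <- matrix(legend_id_t(sg, "BACK"), nrow(main), ncol(main))
      tum <- main == legend_id_t(lg, "TUMOR")
      left <- col(main) <= ncol(main) * runif(1, 0.2, 0.8)
      sub[tum & left] <- legend_id_t(sg, "TUMOR_LUAD")
      sub[tum & !left] <- legend_id_t(sg, "TUMOR_LUSC")
      sub[main == legend_id_t(lg, "TU_STROMA")] <- legend_id_t(sg, "TU_STROMA")
      sub[main == legend_id_t(lg, "MUCIN")] <- legend_id_t(sg, "MUCIN")
      sub_path <- file.path(dir, sprintf("sub_%02d.png", i))
      write_mask(tissue_mask(sub, sg), sub_path)
    }
    rows[[i]] <- tibble::tibble(case_id = sprintf("C%02d", i),
                                slide_id = sprintf("S%02d", i),
                                mask_path = mask_path,
                                subtype_mask_path = sub_path)
  }
  manifest <- dplyr::bind_rows(rows)
  clinical <- tibble::tibble(
    case_id = manifest$case_id,
    time_os = round(rexp(n_cases, 0.02) + 1, 2),
    event_os = rbinom(n_cases, 1, 0.7),
    pT = sample(c("pT1", "pT2", "pT3"), n_cases, TRUE),
    pN = sample(c("pN0", "pN1"), n_cases, TRUE))
  list(manifest = manifest, clinical = clinical)
}
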