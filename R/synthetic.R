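#' Specification for synthetic masks and cohorts
#'
#' The generator emulates the geometry that the quantification layer
#' consumes: a central tumor nodule (epithelial tumor + tumor stroma drawn
#' from a thresholded smooth random field), necrosis and mucin components
#' carved inside the tumor, TLS objects placed intratumorally, immediately
#' peritumorally or distant from the tumor, and a benign surround
#' (lung parenchyma / stroma / background). Planted class fractions are
#' expressed relative to the final tumor + tumor-stroma area, i.e. they are
#' the ground-truth TLS-TD / NECR-TD values, so parameter recovery can be
#' checked directly.
#'
#' The linked survival cohort draws per-case densities and
#' proportional-hazards event times whose log-hazard is linear in TLS-TD
#' (protective) and NECR-TD (adverse); effect sizes are given as hazard
#' ratios per standard deviation of the density.
#'
#' @param canvas_px Square canvas side in pixels.
#' @param mpp Microns per pixel.
#' @param tumor_area_frac Fraction of the canvas covered by the tumor region
#'   before carving.
#' @param stroma_frac Share of the tumor region assigned to TU_STROMA.
#' @param f_necrosis,f_tls,f_mucin Planted fractions (of final tumor +
#'   tumor-stroma area). `f_tls` counts intratumoral + peritumoral TLS.
#' @param tls_mix Named proportions `intratumoral`/`peritumoral`/`distant`
#'   summing to 1.
#' @param peritumoral_dist_um Qualification distance (µm) the placement
#'   respects.
#' @param radius_px Range of planted-disc radii in pixels.
#' @param field_scale_px Correlation length of the random field (default
#'   canvas/32).
#' @param n Cohort size.
#' @param baseline_hazard Baseline event rate per month.
#' @param hr_tls,hr_necr Hazard ratios per 1 SD of the density (protective
#'   `< 1` for TLS, adverse `> 1` for necrosis).
#' @param censoring Target censoring fraction (independent exponential
#'   censoring plus a 120-month administrative cap).
#' @param necrosis_free_frac Fraction of cases with no necrosis at all
#'   (their T/NR is undefined).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(canvas_px = 1024, mpp = 1.0,
                       tumor_area_frac = 0.35, stroma_frac = 0.40,
                       f_necrosis = 0.05, f_tls = 0.02, f_mucin = 0.01,
                       tls_mix = c(intratumoral = 0.5, peritumoral = 0.3,
                                   distant = 0.2),
                       peritumoral_dist_um = 250,
                       radius_px = c(4, 10),
                       field_scale_px = NULL,
                       n = 200, baseline_hazard = 0.01,
                       hr_tls = 0.5, hr_necr = 2.0, censoring = 0.30,
                       necrosis_free_frac = 0.10) {
  spec <- list(canvas_px = as.integer(canvas_px), mpp = mpp,
               tumor_area_frac = tumor_area_frac, stroma_frac = stroma_frac,
               f_necrosis = f_necrosis, f_tls = f_tls, f_mucin = f_mucin,
               tls_mix = tls_mix, peritumoral_dist_um = peritumoral_dist_um,
               radius_px = as.integer(radius_px),
               field_scale_px = field_scale_px %||% max(4, canvas_px / 32),
               n = as.integer(n), baseline_hazard = baseline_hazard,
               hr_tls = hr_tls, hr_necr = hr_necr, censoring = censoring,
               necrosis_free_frac = necrosis_free_frac)
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

validate_synth_spec <- function(spec) {
  fr <- c(spec$f_necrosis, spec$f_tls, spec$f_mucin)
  if (any(fr < 0) || any(fr > 1)) {
    abort("planted fractions must lie in [0, 1]",
          class = "tissuemaps_spec_error")
  }
  if (abs(sum(spec$tls_mix) - 1) > 1e-8 || any(spec$tls_mix < 0)) {
    abort("tls_mix must be non-negative and sum to 1",
          class = "tissuemaps_spec_error")
  }
  mix_ip <- spec$tls_mix[["intratumoral"]] + spec$tls_mix[["peritumoral"]]
  share_i <- if (mix_ip > 0) spec$tls_mix[["intratumoral"]] / mix_ip else 0
  if (spec$f_necrosis + spec$f_mucin + share_i * spec$f_tls > 0.9) {
    abort("within-tumor planted fractions are infeasible (carve > 90% of tumor)",
          class = "tissuemaps_spec_error")
  }
  if (spec$tumor_area_frac <= 0 || spec$tumor_area_frac > 0.6) {
    abort("tumor_area_frac must be in (0, 0.6] so a benign surround remains",
          class = "tissuemaps_spec_error")
  }
  if (spec$n < 2) abort("cohort needs n >= 2", class = "tissuemaps_spec_error")
  if (spec$baseline_hazard <= 0 || spec$hr_tls <= 0 || spec$hr_necr <= 0) {
    abort("hazards must be positive", class = "tissuemaps_spec_error")
  }
  if (spec$censoring < 0 || spec$censoring >= 1) {
    abort("censoring must be in [0, 1)", class = "tissuemaps_spec_error")
  }
  invisible(spec)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Smooth Gaussian random field via FFT low-pass filtering; unit-variance.
smooth_field <- function(n, scale_px) {
  z <- matrix(rnorm(n * n), n)
  fr <- (seq_len(n) - 1) / n
  fr <- ifelse(fr > 0.5, fr - 1, fr)
  h <- exp(-2 * pi^2 * scale_px^2 * outer(fr^2, fr^2, "+"))
  f <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / n^2
  (f - mean(f)) / stats::sd(f)
}

# Plant discs of class_id until target_px pixels are converted.
# dist_mat gates centers (per-radius window) and pixels (fixed window);
# allowed_ids are the classes a disc may overwrite. The last disc is
# truncated to the nearest-to-center pixels so the target is hit exactly
# whenever enough eligible pixels exist.
plant_discs <- function(labels, class_id, target_px, allowed_ids, dist_mat,
                        center_lo, center_hi, pixel_lo, pixel_hi,
                        radius_px, placement, max_iter = 20000) {
  objects <- list()
  planted <- 0L
  nr <- nrow(labels)
  nc <- ncol(labels)
  iter <- 0
  while (planted < target_px && iter < max_iter) {
    iter <- iter + 1
    r <- sample(seq(radius_px[1], radius_px[2]), 1)
    cand <- which(dist_mat >= center_lo(r) & dist_mat <= center_hi(r) &
                    matrix(labels %in% allowed_ids, nr))
    if (length(cand) == 0) {
      if (r > radius_px[1]) next  # retry smaller radii
      abort(paste0("infeasible placement for class id ", class_id,
                   " (", placement, "): no eligible centers"),
            class = "tissuemaps_spec_error")
    }
    ctr <- cand[sample.int(length(cand), 1)]
    c0 <- (ctr - 1) %/% nr + 1
    r0 <- (ctr - 1) %% nr + 1
    rows <- max(1, r0 - r):min(nr, r0 + r)
    cols <- max(1, c0 - r):min(nc, c0 + r)
    dr <- outer(rows - r0, cols - c0, function(a, b) sqrt(a^2 + b^2))
    sel <- which(dr <= r)
    px <- (rep(cols, each = length(rows))[sel] - 1) * nr +
      rep(rows, times = length(cols))[sel]
    ok <- labels[px] %in% allowed_ids &
      dist_mat[px] >= pixel_lo & dist_mat[px] <= pixel_hi
    px <- px[ok]
    d_ctr <- dr[sel][ok]
    if (length(px) == 0) next
    need <- target_px - planted
    if (length(px) > need) px <- px[order(d_ctr)][seq_len(need)]
    labels[px] <- class_id
    planted <- planted + length(px)
    objects[[length(objects) + 1]] <-
      tibble(placement = placement, center_row = r0, center_col = c0,
             radius_px = r, area_px = length(px))
  }
  if (planted < target_px) {
    abort(paste0("could not place enough ", placement, " pixels for class id ",
                 class_id, " (", planted, "/", target_px, ")"),
          class = "tissuemaps_spec_error")
  }
  list(labels = labels, objects = bind_rows(objects))
}

#' Generate a synthetic tissue mask with known ground truth
#'
#' See [synth_spec()] for what is emulated. The generator is a pure function
#' of `(spec, seed)`: the same pair yields a bit-identical mask.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed fixing all randomness.
#' @param slide_id Optional slide id for the mask.
#' @return A list with `mask` (a [tissue_mask()]) and `truth`: realized
#'   planted areas, the ground-truth densities `tls_td`, `necr_td`, `t_nr`,
#'   and a per-disc `objects` tibble with the placement category each disc
#'   was constructed under.
#' @export
generate_mask <- function(spec, seed, slide_id = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, generate_mask_impl(spec, slide_id))
}

generate_mask_impl <- function(spec, slide_id) {
  legend <- default_legend()
  id <- function(nm) legend_id(legend, nm)
  n <- spec$canvas_px
  peri_px <- spec$peritumoral_dist_um / spec$mpp

  # tumor support: smooth field plus a central bump so the far corners stay
  # clear of the tumor (room for distant TLS placement)
  ax <- (seq_len(n) - (n + 1) / 2) / n
  bump <- exp(-outer(ax^2, ax^2, "+") / (2 * 0.18^2))
  f1 <- smooth_field(n, spec$field_scale_px) + 3 * (bump - mean(bump)) / stats::sd(bump)
  tumor <- f1 > quantile(f1, 1 - spec$tumor_area_frac)

  labels <- matrix(id("LUNG_BENIGN"), n, n)
  # benign surround partition
  f2 <- smooth_field(n, spec$field_scale_px / 2)
  outside <- !tumor
  q <- quantile(f2[outside], c(0.5, 0.8))
  labels[outside & f2 > q[1] & f2 <= q[2]] <- id("STROMA")
  labels[outside & f2 > q[2]] <- id("BACK")
  # tumor region: TUMOR with a TU_STROMA component
  f3 <- smooth_field(n, spec$field_scale_px / 2)
  stroma_cut <- quantile(f3[tumor], spec$stroma_frac)
  labels[tumor] <- ifelse(f3[tumor] <= stroma_cut, id("TU_STROMA"), id("TUMOR"))

  # planted-area targets relative to the final carved denominator; f_tls is
  # the QUALIFIED (intratumoral + peritumoral) density, so the mix shares are
  # renormalized over those two categories and distant TLS is planted on top
  a0 <- sum(tumor)
  mix <- spec$tls_mix
  mix_ip <- mix[["intratumoral"]] + mix[["peritumoral"]]
  share_i <- if (mix_ip > 0) mix[["intratumoral"]] / mix_ip else 0
  share_p <- if (mix_ip > 0) mix[["peritumoral"]] / mix_ip else 0
  share_d <- if (mix_ip > 0) mix[["distant"]] / mix_ip else
    as.numeric(spec$f_tls > 0)
  denom_target <- a0 / (1 + spec$f_necrosis + spec$f_mucin +
                          share_i * spec$f_tls)
  t_necr <- round(spec$f_necrosis * denom_target)
  t_mucin <- round(spec$f_mucin * denom_target)
  t_tls_i <- round(share_i * spec$f_tls * denom_target)
  t_tls_p <- round(share_p * spec$f_tls * denom_target)
  t_tls_d <- round(share_d * spec$f_tls * denom_target)

  dint <- matrix(as.numeric(EBImage::distmap(matrix(as.numeric(tumor), n))), n)
  dout <- matrix(as.numeric(EBImage::distmap(matrix(as.numeric(!tumor), n))), n)
  tumor_ids <- id(c("TUMOR", "TU_STROMA"))
  benign_ids <- id(c("LUNG_BENIGN", "STROMA", "BACK"))
  objects <- list()

  plant <- function(labels, class_nm, target, allowed, dmat, clo, chi, plo, phi,
                    placement) {
    if (target <= 0) return(list(labels = labels, objects = tibble()))
    plant_discs(labels, id(class_nm), target, allowed, dmat,
                clo, chi, plo, phi, spec$radius_px, placement)
  }

  res <- plant(labels, "NECROSIS", t_necr, tumor_ids, dint,
               function(r) 3, function(r) Inf, 0.9, Inf, "intratumoral")
  labels <- res$labels; objects$necr <- mutate(res$objects, class_name = "NECROSIS")

  res <- plant(labels, "MUCIN", t_mucin, tumor_ids, dint,
               function(r) 3, function(r) Inf, 0.9, Inf, "intratumoral")
  labels <- res$labels; objects$mucin <- mutate(res$objects, class_name = "MUCIN")

  res <- plant(labels, "TLS", t_tls_i, tumor_ids, dint,
               function(r) r + 1.5, function(r) Inf, 0.9, Inf, "intratumoral")
  labels <- res$labels; objects$tls_i <- mutate(res$objects, class_name = "TLS")

  res <- plant(labels, "TLS", t_tls_p, benign_ids, dout,
               function(r) r + 3, function(r) max(r + 3, peri_px - 1),
               2.05, peri_px, "peritumoral")
  labels <- res$labels; objects$tls_p <- mutate(res$objects, class_name = "TLS")

  res <- plant(labels, "TLS", t_tls_d, benign_ids, dout,
               function(r) peri_px + r + 5, function(r) Inf,
               peri_px + 2.5, Inf, "distant")
  labels <- res$labels; objects$tls_d <- mutate(res$objects, class_name = "TLS")

  mask <- tissue_mask(labels, legend, mpp = spec$mpp, slide_id = slide_id)
  prof <- profile_areas(mask)
  px <- setNames(prof$pixels, prof$class_name)
  denom <- px[["TUMOR"]] + px[["TU_STROMA"]]
  obj <- bind_rows(objects)
  area_by <- function(p) if (nrow(obj) == 0) 0 else
    sum(obj$area_px[obj$class_name == "TLS" & obj$placement %in% p])
  tls_counted <- area_by(c("intratumoral", "peritumoral"))
  truth <- list(
    denom_px = denom,
    tls_area_px = tls_counted,
    tls_distant_px = area_by("distant"),
    necrosis_area_px = t_necr,
    mucin_area_px = t_mucin,
    tls_td = tls_counted / denom,
    necr_td = t_necr / denom,
    t_nr = if (t_necr > 0) tls_counted / t_necr else NA_real_,
    objects = obj
  )
  list(mask = mask, truth = truth)
}

#' Generate a synthetic survival cohort with known generative model
#'
#' Per-case TLS-TD and NECR-TD densities are drawn from log-normal
#' distributions at the magnitudes seen on real slides (TLS-TD of order
#' 1e-3, NECR-TD of order 1e-2; a configurable fraction of cases has no
#' necrosis at all, leaving T/NR undefined). Event times for OS, CSS and PFS
#' follow proportional hazards with log-hazard linear in the densities
#' (standardized internally; `hr_tls`/`hr_necr` are per SD). pT and pN
#' categories are sampled with a positive association to NECR-TD.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per case: `case_id`, `tls_td`, `necr_td`,
#'   `t_nr`, `time_os`/`event_os`, `time_css`/`event_css`,
#'   `time_pfs`/`event_pfs`, `pT`, `pN`. The generative coefficients are
#'   attached as attribute `"truth"`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n
  tls <- stats::rlnorm(n, meanlog = log(2e-3), sdlog = 0.8)
  necr <- stats::rlnorm(n, meanlog = log(3e-2), sdlog = 1.0)
  necr[runif(n) < spec$necrosis_free_frac] <- 0
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  lp <- log(spec$hr_tls) * z(tls) + log(spec$hr_necr) * z(necr)

  draw_endpoint <- function(h0) {
    t_event <- rexp(n, rate = h0 * exp(lp))
    cens_rate <- h0 * spec$censoring / max(1e-9, 1 - spec$censoring)
    t_cens <- pmin(rexp(n, rate = max(cens_rate, 1e-9)), 120)
    tibble(time = pmax(pmin(t_event, t_cens), 1e-3),
           event = as.integer(t_event <= t_cens))
  }
  os <- draw_endpoint(spec$baseline_hazard)
  css <- draw_endpoint(spec$baseline_hazard * 0.8)
  pfs <- draw_endpoint(spec$baseline_hazard * 1.5)

  lat_t <- 0.5 * z(necr) + rnorm(n)
  pT <- cut(lat_t, breaks = quantile(lat_t, c(0, 0.35, 0.70, 0.90, 1)),
            labels = c("pT1", "pT2", "pT3", "pT4"), include.lowest = TRUE)
  lat_n <- 0.4 * z(necr) + rnorm(n)
  pN <- cut(lat_n, breaks = quantile(lat_n, c(0, 0.55, 0.85, 1)),
            labels = c("pN0", "pN1", "pN2"), include.lowest = TRUE)

  out <- tibble(
    case_id = sprintf("case_%04d", seq_len(n)),
    tls_td = tls, necr_td = necr,
    t_nr = ifelse(necr > 0, tls / necr, NA_real_),
    time_os = os$time, event_os = os$event,
    time_css = css$time, event_css = css$event,
    time_pfs = pfs$time, event_pfs = pfs$event,
    pT = pT, pN = pN
  )
  attr(out, "truth") <- list(log_hr_tls_per_sd = log(spec$hr_tls),
                             log_hr_necr_per_sd = log(spec$hr_necr),
                             baseline_hazard = spec$baseline_hazard)
  out
}

#' Simulate a cohort with a planted prognostic cutoff
#'
#' Draws a uniform parameter on `[0, 1]` and gives cases above the planted
#' cutpoint a hazard `hr` times the baseline — a pure threshold effect, the
#' generative model under which optimal-cutpoint recovery is meaningful.
#'
#' @param n Cohort size.
#' @param hr Hazard ratio of the high group.
#' @param cutpoint Planted cutoff on the parameter (also its quantile, since
#'   the parameter is uniform).
#' @param baseline_hazard Events per month in the low group.
#' @param censoring Target censoring fraction.
#' @param seed Integer seed.
#' @return A list: `data` (tibble `value`, `time`, `event`) and `cutpoint`.
#' @export
simulate_threshold_cohort <- function(n = 200, hr = 3, cutpoint = 0.5,
                                      baseline_hazard = 0.02,
                                      censoring = 0.30, seed = 1) {
  with_seed(seed, {
    value <- runif(n)
    h <- baseline_hazard * ifelse(value > cutpoint, hr, 1)
    t_event <- rexp(n, h)
    cens_rate <- baseline_hazard * censoring / (1 - censoring)
    t_cens <- pmin(rexp(n, cens_rate), 120)
    list(data = tibble(value = value,
                       time = pmax(pmin(t_event, t_cens), 1e-3),
                       event = as.integer(t_event <= t_cens)),
         cutpoint = cutpoint)
  })
}
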