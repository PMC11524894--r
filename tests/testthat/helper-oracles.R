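# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately share no code with the implementation paths they
# check.

rand_mask <- function(h, w, legend = default_legend(), seed = 1,
                      ids = legend$class_id, mpp = 1) {
  set.seed(seed)
  tissue_mask(matrix(sample(ids, h * w, replace = TRUE), h, w),
              legend, mpp = mpp)
}

# per-pixel tally oracle for profile_areas
brute_profile <- function(mask, restrict_to = NULL) {
  counts <- setNames(rep(0L, nrow(mask$legend)), mask$legend$class_name)
  for (r in seq_len(nrow(mask$labels))) {
    for (c in seq_len(ncol(mask$labels))) {
      if (!is.null(restrict_to) && !restrict_to[r, c]) next
      nm <- mask$legend$class_name[match(mask$labels[r, c],
                                         mask$legend$class_id)]
      counts[nm] <- counts[nm] + 1L
    }
  }
  counts
}

# pixel-set Dice oracle
brute_dice <- function(truth, pred, region = NULL) {
  keep <- if (is.null(region)) rep(TRUE, length(truth$labels)) else as.logical(region)
  t <- truth$labels[keep]; p <- pred$labels[keep]
  vapply(truth$legend$class_id, function(id) {
    ts <- sum(t == id); ps <- sum(p == id)
    if (ts + ps == 0) return(NA_real_)
    2 * sum(t == id & p == id) / (ts + ps)
  }, 0)
}

# flood-fill labeling oracle (stack of (row, col) pairs per component)
flood_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0) next
    nxt <- nxt + 1L
    stack_r <- r0; stack_c <- c0
    lab[r0, c0] <- nxt
    while (length(stack_r) > 0) {
      r <- stack_r[length(stack_r)]; c <- stack_c[length(stack_c)]
      stack_r <- stack_r[-length(stack_r)]; stack_c <- stack_c[-length(stack_c)]
      for (k in seq_len(nrow(nb))) {
        rn <- r + nb[k, 1]; cn <- c + nb[k, 2]
        if (rn >= 1 && rn <= nr && cn >= 1 && cn <= nc &&
            mask[rn, cn] && lab[rn, cn] == 0) {
          lab[rn, cn] <- nxt
          stack_r <- c(stack_r, rn); stack_c <- c(stack_c, cn)
        }
      }
    }
  }
  lab
}

# exhaustive min pairwise pixel-center distance between an index set and a
# logical reference region
brute_min_dist <- function(pixels, region) {
  nr <- nrow(region)
  reg <- which(region)
  if (length(reg) == 0) return(Inf)
  pr <- (pixels - 1) %% nr + 1; pc <- (pixels - 1) %/% nr + 1
  rr <- (reg - 1) %% nr + 1; rc <- (reg - 1) %/% nr + 1
  min(sqrt(outer(pr, rr, "-")^2 + outer(pc, rc, "-")^2))
}

# qualification oracle mirroring the stated rule from pairwise distances
brute_qualify <- function(objects, mask, peritumoral_dist_um, connectivity = 8) {
  touch <- if (connectivity == 8) sqrt(2) else 1
  vapply(seq_len(nrow(objects)), function(i) {
    cls <- objects$class_name[i]
    ref_classes <- setdiff(
      mask$legend$class_name[mask$legend$group == "tumor_region"], cls)
    region <- matrix(mask$labels %in%
                       mask$legend$class_id[match(ref_classes,
                                                  mask$legend$class_name)],
                     nrow(mask$labels))
    d <- brute_min_dist(objects$pixels[[i]], region)
    if (d <= touch + 1e-9) "intratumoral"
    else if (d * mask$mpp <= peritumoral_dist_um + 1e-9) "peritumoral"
    else "non_tumor_associated"
  }, "")
}

# small planted-layout builder for qualification tests: a tumor disc plus
# TLS/NECROSIS discs at controlled distances
disc_pixels <- function(nr, nc, r0, c0, rad) {
  idx <- which(outer(seq_len(nr) - r0, seq_len(nc) - c0,
                     function(a, b) sqrt(a^2 + b^2)) <= rad)
  idx
}

build_layout <- function(n = 48, tumor_rad = 12, seed = 1,
                         legend = default_legend()) {
  set.seed(seed)
  labels <- matrix(legend_id_t(legend, "LUNG_BENIGN"), n, n)
  ctr <- n / 2
  labels[disc_pixels(n, n, ctr, ctr, tumor_rad)] <- legend_id_t(legend, "TUMOR")
  labels
}

legend_id_t <- function(legend, nm) legend$class_id[match(nm, legend$class_name)]

# explicit risk-table log-rank oracle (O - E / V over event times)
brute_logrank <- function(time, event, group) {
  lv <- sort(unique(group))
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == lv[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == lv[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * n1 / n * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v > 0) (o1 - e1)^2 / v else 0
}

# mask fixture with explicit class counts laid out in columns
counts_mask <- function(counts, legend = default_legend(), mpp = 1, ncol = NULL) {
  total <- sum(counts)
  ncol <- ncol %||% ceiling(sqrt(total))
  nrow <- ceiling(total / ncol)
  pad <- nrow * ncol - total
  ids <- c(rep(legend_id_t(legend, names(counts)), counts),
           rep(legend_id_t(legend, "BACK"), pad))
  tissue_mask(matrix(ids, nrow, ncol), legend, mpp = mpp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
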