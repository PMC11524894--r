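#' Read and validate a slide manifest
#'
#' The manifest lists the mask files of a cohort, one row per slide:
#' `case_id`, `slide_id`, `mask_path` and optionally `subtype_mask_path`.
#' Slide ids must be unique; paths are resolved relative to the manifest
#' file when `path` is a file.
#'
#' @param path CSV path, or a data frame already in manifest shape.
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  m <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    out <- readr::read_csv(path, show_col_types = FALSE)
    for (col in intersect(c("mask_path", "subtype_mask_path"), names(out))) {
      out[[col]] <- ifelse(is.na(out[[col]]) | file.exists(out[[col]]),
                           out[[col]],
                           file.path(dirname(path), out[[col]]))
    }
    out
  }
  need <- c("case_id", "slide_id", "mask_path")
  if (!all(need %in% names(m))) {
    abort(paste0("manifest needs columns: ", paste(need, collapse = ", ")),
          class = "tissuemaps_manifest_error")
  }
  if (anyDuplicated(m$slide_id)) {
    abort("manifest slide_ids must be unique",
          class = "tissuemaps_manifest_error")
  }
  if (!"subtype_mask_path" %in% names(m)) m$subtype_mask_path <- NA_character_
  m
}

#' Pipeline configuration
#'
#' All tunable thresholds of the analysis in one auditable place; every run
#' log records them. Defaults follow the platform conventions: 512 px tiles
#' at MPP 1.0, 8-connectivity components, 250 µm "immediate peritumoral"
#' distance, a closed 40-60% borderline zone, and a cutpoint grid over
#' percentiles 10-90 in steps of 2.5 with a 10% minimum group size.
#'
#' @param mpp Microns per pixel of the input masks.
#' @param tile_size_px Tile side for inference harness runs.
#' @param connectivity Component connectivity (8 or 4).
#' @param peritumoral_dist_um Object-qualification distance, µm.
#' @param borderline_pct Closed borderline interval for subtype calls.
#' @param cutoff_probs Quantile grid for the optimal-cutpoint scan.
#' @param min_group_frac Minimum group fraction at the cutpoint.
#' @param min_cohort_for_survival Smallest cohort the survival stage runs on.
#' @param seed Seed recorded with the run.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(mpp = 1.0, tile_size_px = 512, connectivity = 8,
                            peritumoral_dist_um = 250,
                            borderline_pct = c(40, 60),
                            cutoff_probs = seq(0.10, 0.90, by = 0.025),
                            min_group_frac = 0.10,
                            min_cohort_for_survival = 20,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full quantification pipeline over a cohort
#'
#' Chains the platform stages for every slide of a manifest: area profiling,
#' optional LUAD/LUSC subtyping, prognostic scoring; pools slides to cases;
#' then (given a clinical table with enough cases) dichotomizes each
#' prognostic parameter at its optimal cutpoint, assigns the T+NR groups and
#' fits Kaplan-Meier, log-rank and Cox models per endpoint. A failing slide
#' is logged and flagged and the remaining slides are still processed
#' (fail-soft); callers can inspect `$failures`.
#'
#' Outputs written under `out_dir`: `profiles.csv`, `scores_slides.csv`,
#' `scores_cases.csv`, `subtype_slides.csv`/`subtype_cases.csv` (when
#' subtype masks exist), `cutoffs.json`, `km_tables.csv`, `cox_results.csv`
#' and `run_log.json` (config, package version, per-slide status). Output
#' tables are deterministic: a re-run with identical inputs and seed is
#' byte-identical.
#'
#' @param manifest Manifest (path or data frame), see [read_manifest()].
#' @param clinical Optional clinical table (path or data frame) with
#'   `case_id`, endpoint columns (`time_os`/`event_os`, `time_css`/...,
#'   `time_pfs`/...) and `pT`, `pN`.
#' @param out_dir Output directory (created if needed).
#' @param legend A [class_legend()] for the main masks.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the tables, the cutoffs, and `failures`.
#' @export
run_pipeline <- function(manifest, clinical = NULL, out_dir,
                         legend = default_legend(),
                         config = pipeline_config()) {
  manifest <- read_manifest(manifest)
  if (!is.null(clinical) && !is.data.frame(clinical)) {
    clinical <- readr::read_csv(clinical, show_col_types = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failures <- list()
  profiles <- list(); scores <- list(); sub_calls <- list()

  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      mask <- read_mask(row$mask_path, legend, mpp = config$mpp,
                        slide_id = row$slide_id)
      prof <- mutate(profile_areas(mask), case_id = row$case_id, .before = 1)
      sc <- mutate(prognostic_scores(
        mask, peritumoral_dist_um = config$peritumoral_dist_um,
        connectivity = config$connectivity), case_id = row$case_id, .before = 1)
      sub <- NULL
      if (!is.na(row$subtype_mask_path)) {
        smask <- read_mask(row$subtype_mask_path, subtype_legend(),
                           mpp = config$mpp, slide_id = row$slide_id)
        sub <- mutate(classify_slide(mask, smask,
                                     borderline = config$borderline_pct),
                      case_id = row$case_id, .before = 1)
      }
      list(prof = prof, sc = sc, sub = sub)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        tibble(case_id = row$case_id, slide_id = row$slide_id,
               error = conditionMessage(res))
      next
    }
    profiles[[i]] <- res$prof
    scores[[i]] <- res$sc
    if (!is.null(res$sub)) sub_calls[[i]] <- res$sub
  }

  profiles <- bind_rows(profiles)
  scores_slides <- bind_rows(scores)
  failures <- bind_rows(failures)
  out <- list(profiles = profiles, scores_slides = scores_slides,
              failures = failures)
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
  readr::write_csv(scores_slides, file.path(out_dir, "scores_slides.csv"))

  if (nrow(scores_slides) > 0) {
    scores_cases <- pool_case_scores(scores_slides)
    out$scores_cases <- scores_cases
  } else {
    scores_cases <- NULL
  }

  if (length(sub_calls) > 0) {
    sub_slides <- bind_rows(sub_calls)
    sub_cases <- sub_slides |>
      dplyr::group_split(.data$case_id) |>
      map(~ aggregate_case(.x, case_id = .x$case_id[1],
                           borderline = config$borderline_pct)) |>
      bind_rows()
    readr::write_csv(sub_slides, file.path(out_dir, "subtype_slides.csv"))
    readr::write_csv(sub_cases, file.path(out_dir, "subtype_cases.csv"))
    out$subtype_slides <- sub_slides
    out$subtype_cases <- sub_cases
  }

  survival_run <- FALSE
  if (!is.null(clinical) && !is.null(scores_cases)) {
    cohort <- left_join(scores_cases, clinical, by = "case_id")
    out$cohort <- cohort
    if (nrow(cohort) >= config$min_cohort_for_survival) {
      surv <- tryCatch(
        run_survival_stage(cohort, config, out_dir),
        error = function(e) {
          failures <<- bind_rows(failures,
                                 tibble(case_id = NA_character_,
                                        slide_id = "survival_stage",
                                        error = conditionMessage(e)))
          NULL
        })
      if (!is.null(surv)) {
        out <- c(out, surv)
        survival_run <- TRUE
      }
    }
  }
  if (!is.null(scores_cases)) {
    readr::write_csv(scores_with_groups(out), file.path(out_dir, "scores_cases.csv"))
  }
  out$failures <- failures

  log <- list(
    package_version = as.character(utils::packageVersion("tissuemaps")),
    config = unclass(config),
    config_hash = config_hash(config),
    n_slides = nrow(manifest),
    n_failed = nrow(failures),
    survival_stage_run = survival_run,
    slides = manifest$slide_id,
    failed = if (nrow(failures)) failures$slide_id else character()
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

scores_with_groups <- function(out) {
  sc <- out$scores_cases
  if (!is.null(out$groups)) {
    sc <- left_join(sc, out$groups, by = "case_id")
  }
  sc
}

run_survival_stage <- function(cohort, config, out_dir) {
  ep <- detect_endpoints(cohort)
  if (length(ep) == 0) {
    abort("clinical table has no endpoint columns",
          class = "tissuemaps_value_error")
  }
  primary <- ep[[1]]  # one cutoff per parameter, reused for all endpoints
  params <- c("tls_td", "necr_td", "t_nr")
  cutoffs <- list()
  groups <- tibble(case_id = cohort$case_id)
  for (p in params) {
    co <- find_optimal_cutoff(cohort, !!rlang::sym(p),
                              !!rlang::sym(primary$time),
                              !!rlang::sym(primary$event),
                              probs = config$cutoff_probs,
                              min_group_frac = config$min_group_frac)
    cutoffs[[p]] <- glance(co)
    groups[[paste0(p, "_group")]] <- as.character(dichotomize(cohort[[p]],
                                                              co$cutoff))
  }
  groups$pg <- as.character(
    assign_prognostic_group(groups$tls_td_group, groups$necr_td_group))

  km_tables <- list(); cox_rows <- list()
  cohort_g <- left_join(cohort, groups, by = "case_id")
  for (e in ep) {
    for (p in params) {
      gcol <- paste0(p, "_group")
      d <- cohort_g[!is.na(cohort_g[[gcol]]), ]
      km <- km_estimate(d, !!rlang::sym(e$time), !!rlang::sym(e$event),
                        group = !!rlang::sym(gcol))
      km_tables[[paste(p, e$name)]] <-
        mutate(as_tibble(km), parameter = p, endpoint = e$name, .before = 1)
      covs <- c(gcol, intersect(c("pT", "pN"), names(d)))
      fit <- tryCatch(cox_fit(d, e$time, e$event, covs), error = function(x) NULL)
      if (!is.null(fit)) {
        cox_rows[[paste(p, e$name)]] <-
          mutate(tidy(fit), parameter = p, endpoint = e$name,
                 model = "multivariate", .before = 1)
      }
    }
  }
  readr::write_csv(bind_rows(km_tables), file.path(out_dir, "km_tables.csv"))
  readr::write_csv(bind_rows(cox_rows), file.path(out_dir, "cox_results.csv"))
  jsonlite::write_json(
    c(list(peritumoral_dist_um = config$peritumoral_dist_um,
           primary_endpoint = primary$name),
      lapply(cutoffs, as.list)),
    file.path(out_dir, "cutoffs.json"), auto_unbox = TRUE, digits = NA)
  list(cutoffs = cutoffs, groups = groups,
       km_tables = bind_rows(km_tables), cox_results = bind_rows(cox_rows))
}

detect_endpoints <- function(cohort) {
  eps <- list(list(name = "os", time = "time_os", event = "event_os"),
              list(name = "css", time = "time_css", event = "event_css"),
              list(name = "pfs", time = "time_pfs", event = "event_pfs"))
  Filter(function(e) all(c(e$time, e$event) %in% names(cohort)), eps)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
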