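#' Default demo run configuration
#'
#' A complete, validated configuration for the end-to-end study replica:
#' a cross-sectional cohort (with 2D measure sheets carrying two injected
#' patient-vs-control patches), a longitudinal cohort realising the four
#' evolution patterns, and the standard thresholds (voxel p < .01, cluster
#' p < .05, FWHM 10 mm, >10% lesion-voxel inclusion, >10-voxel cluster
#' reporting, q = .05).
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a validated `run_config` list.
#' @export
demo_run_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  cfg <- list(
    grid = list(shape = c(32L, 32L, 32L), voxel_size = 2),
    atlas_seed = seed + 1L,
    cohort = list(n_patients = 180L, n_controls = 100L, seed = seed + 2L),
    longitudinal = list(n_patients = 80L, n_controls = 12L,
                        visit_months = c(0.25, 1, 3, 7),
                        seed = seed + 3L),
    sheet = list(shape = c(64L, 64L), spacing_mm = 2, fwhm_mm = 10,
                 noise_sd = 1,
                 effects = data.frame(
                   group = c("patient", "patient"),
                   measure = c("thickness", "area"),
                   ci = c(18L, 44L), cj = c(18L, 44L),
                   halfwidth = c(4L, 4L),
                   amplitude = c(-1.0, 1.0))),
    discovery_fraction = 0.63,
    stages = list(impairment = TRUE, cluster_glm = TRUE, roi_stats = TRUE,
                  vlsm = TRUE, lmm = TRUE),
    thresholds = list(min_incidence = 0.10, min_cluster = 10L,
                      voxel_p = 0.01, cluster_p = 0.05, q = 0.05,
                      n_sims = 1000L, fwhm_mm = 10),
    mc_seed = seed + 4L,
    write_volumes = FALSE)
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Accepts a config list or a YAML file path, checks types and ranges,
#' rejects unknown keys, and returns the normalised configuration. Every
#' stochastic stage must carry an explicit seed.
#'
#' @param config list or path to a YAML file.
#' @return the validated `run_config` list (invisibly usable directly by
#'   [run_pipeline()]).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (!is.null(config$sheet$effects))
      config$sheet$effects <- as.data.frame(config$sheet$effects)
  }
  allowed <- c("grid", "atlas_seed", "cohort", "longitudinal", "sheet",
               "discovery_fraction", "stages", "thresholds", "mc_seed",
               "write_volumes")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("grid", "cohort", "longitudinal", "thresholds",
                       "stages"), names(config))
  if (length(missing) > 0L)
    stop("missing config keys: ", paste(missing, collapse = ", "))
  th <- config$thresholds
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("config: ", msg)
  chk(is.numeric(th$min_incidence) && th$min_incidence >= 0 &&
        th$min_incidence < 1, "min_incidence must lie in [0, 1)")
  chk(th$min_cluster >= 0, "min_cluster must be >= 0")
  chk(th$voxel_p > 0 && th$voxel_p < 1, "voxel_p must lie in (0, 1)")
  chk(th$cluster_p > 0 && th$cluster_p < 1, "cluster_p must lie in (0, 1)")
  chk(th$q > 0 && th$q < 1, "q must lie in (0, 1)")
  chk(th$n_sims >= 100, "n_sims must be >= 100")
  chk(th$fwhm_mm > 0, "fwhm_mm must be positive")
  chk(is.numeric(config$atlas_seed), "atlas_seed is required")
  chk(is.numeric(config$cohort$seed), "cohort seed is required")
  chk(is.numeric(config$longitudinal$seed), "longitudinal seed is required")
  if (isTRUE(config$stages$cluster_glm))
    chk(is.numeric(config$mc_seed),
        "mc_seed is required when the cluster_glm stage is enabled")
  df <- config$discovery_fraction
  chk(is.null(df) || (df > 0 && df < 1),
      "discovery_fraction must lie in (0, 1)")
  config
}

#' Run the full study replica
#'
#' Executes the stages in dependency order: simulate (cross-sectional +
#' longitudinal cohorts), CST impairment profiling, discovery/replication
#' cluster mapping on the measure sheets, ROI-level statistics (ANCOVA,
#' WE_FM and CST-impairment partial correlations), VLSM per hemisphere
#' group, and the longitudinal mixed-model stage with pattern labels.
#' Stage tables are written under `out_dir` together with a JSON manifest
#' recording seeds and outputs; a rerun with the same config reproduces the
#' tables exactly.
#'
#' @param config a validated `run_config` (see [demo_run_config()],
#'   [validate_config()]).
#' @param out_dir output directory (created).
#' @return list with all stage results (`cohort`, `longit`, `impairment`,
#'   `cluster_glm`, `roi_stats`, `vlsm`, `lmm`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(package_version = as.character(utils::packageVersion("lesionmap")),
                   stages = list(), outputs = character())
  res <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    out
  }
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, name)
  }

  res$grid <- do.call(grid_spec, config$grid)
  res$atlas <- stage("atlas", make_fiber_atlas(res$grid, config$atlas_seed))

  res$cohort <- stage("simulate_cross_sectional", {
    cc <- do.call(cohort_config, c(config$cohort, list(sheet = config$sheet)))
    simulate_cohort(cc, res$grid, res$atlas)
  })
  res$longit <- stage("simulate_longitudinal", {
    lc <- do.call(cohort_config, config$longitudinal)
    simulate_cohort(lc, res$grid, res$atlas)
  })
  wtsv(res$cohort$subjects, "simulate/subjects.tsv")
  wtsv(chronic_table(res$cohort$measures), "simulate/measures_chronic.tsv")
  wtsv(res$longit$measures, "simulate/measures_longitudinal.tsv")
  if (isTRUE(config$write_volumes)) {
    write_fiber_atlas(res$atlas, file.path(out_dir, "atlas"))
    dir.create(file.path(out_dir, "lesions"), showWarnings = FALSE)
    for (m in res$cohort$masks)
      write_lesion(m, file.path(out_dir, "lesions",
                                paste0(m$subject_id, ".nii.gz")))
    inc <- incidence_map(res$cohort$masks)
    write_volume(inc$counts, res$grid, file.path(out_dir, "lesions",
                                                 "incidence.nii.gz"))
  }

  chronic <- chronic_table(res$cohort$measures)
  subjects <- res$cohort$subjects

  if (isTRUE(config$stages$impairment)) {
    res$impairment <- stage("impairment", {
      pats <- subjects[subjects$is_patient, ]
      impairment_table(res$cohort$masks[pats$subject_id], res$atlas,
                       pats$hemisphere)
    })
    wtsv(res$impairment, "impairment/profiles.tsv")
  }

  if (isTRUE(config$stages$cluster_glm)) {
    res$cluster_glm <- stage("cluster_glm", {
      pats <- which(subjects$is_patient)
      ctrl <- which(!subjects$is_patient)
      ndisc <- round(length(pats) * config$discovery_fraction)
      disc <- c(pats[seq_len(ndisc)], ctrl)
      repl <- c(pats[-seq_len(ndisc)], ctrl)
      out <- list()
      for (ms in names(res$cohort$sheets)) {
        sh <- res$cohort$sheets[[ms]]
        design <- function(rows) data.frame(
          group = factor(ifelse(subjects$is_patient[rows], "patient", "HC"),
                         levels = c("HC", "patient")),
          age = subjects$age[rows], sex = subjects$sex[rows],
          scanner = subjects$scanner[rows],
          global = sh$global[rows])
        stat <- fit_pointwise_glm(sh$values[disc, , drop = FALSE], sh$shape,
                                  design(disc))
        stat <- monte_carlo_cluster_correct(
          stat, n_sims = th$n_sims, voxel_p = th$voxel_p,
          cluster_alpha = th$cluster_p, fwhm_mm = th$fwhm_mm,
          spacing_mm = config$sheet$spacing_mm, seed = config$mc_seed)
        rois <- replicate_rois(stat, sh$values[repl, , drop = FALSE],
                               sh$shape, design(repl), alpha = 0.05)
        out[[ms]] <- list(stat = stat, rois = rois)
      }
      out
    })
    ctab <- do.call(rbind, lapply(names(res$cluster_glm), function(ms) {
      cl <- res$cluster_glm[[ms]]$stat$clusters
      if (nrow(cl) == 0L) return(NULL)
      cbind(measure = ms, cl)
    }))
    if (!is.null(ctab)) wtsv(ctab, "cluster_glm/clusters.tsv")
    rtab <- do.call(rbind, lapply(names(res$cluster_glm), function(ms) {
      rois <- res$cluster_glm[[ms]]$rois
      if (length(rois) == 0L) return(NULL)
      data.frame(measure = ms,
                 roi = vapply(rois, `[[`, character(1), "name"),
                 sign = vapply(rois, `[[`, numeric(1), "sign"),
                 n_points = vapply(rois, `[[`, numeric(1), "n_points"),
                 center_i = vapply(rois, function(r) mean(r$indices[, 1]), numeric(1)),
                 center_j = vapply(rois, function(r) mean(r$indices[, 2]), numeric(1)))
    }))
    if (!is.null(rtab)) wtsv(rtab, "cluster_glm/confirmed_rois.tsv")
  }

  if (isTRUE(config$stages$roi_stats)) {
    res$roi_stats <- stage("roi_stats", {
      rms <- unique(chronic[, c("roi", "measure")])
      anc <- do.call(rbind, lapply(seq_len(nrow(rms)), function(i) {
        sub <- chronic[chronic$roi == rms$roi[i] &
                         chronic$measure == rms$measure[i], ]
        cbind(roi = rms$roi[i], measure = rms$measure[i],
              ancova_three_group(sub$value, sub$group,
                                 sub[, c("age", "sex", "scanner")]))
      }))
      pat <- chronic[chronic$group != "HC", ]
      per_hemi <- function(f) do.call(rbind, lapply(c("left", "right"),
        function(h) cbind(hemisphere = h,
                          f(pat[pat$hemisphere == h, ], q = th$q))))
      list(ancova = anc,
           wefm = per_hemi(wefm_correlations),
           cst = per_hemi(cst_correlations))
    })
    wtsv(res$roi_stats$ancova, "roi_stats/ancova.tsv")
    wtsv(res$roi_stats$wefm, "roi_stats/wefm_partial_correlations.tsv")
    wtsv(res$roi_stats$cst, "roi_stats/cst_correlations.tsv")
  }

  if (isTRUE(config$stages$vlsm)) {
    res$vlsm <- stage("vlsm", {
      pat <- chronic[chronic$group != "HC", ]
      rms <- unique(pat[, c("roi", "measure")])
      out <- list()
      for (h in c("left", "right")) {
        hp <- subjects[subjects$is_patient & subjects$hemisphere == h, ]
        out[[h]] <- vlsm_batch(res$cohort$masks[hp$subject_id],
                               pat[pat$hemisphere == h, ], rms,
                               min_incidence = th$min_incidence,
                               min_cluster = th$min_cluster, q = th$q)
      }
      out
    })
    vtab <- do.call(rbind, lapply(c("left", "right"), function(h) {
      do.call(rbind, lapply(names(res$vlsm[[h]]), function(nm) {
        cl <- res$vlsm[[h]][[nm]]$clusters
        if (nrow(cl) == 0L) return(NULL)
        cbind(hemisphere = h, outcome = nm, cl)
      }))
    }))
    if (!is.null(vtab)) wtsv(vtab, "vlsm/clusters.tsv")
  }

  if (isTRUE(config$stages$lmm)) {
    res$lmm <- stage("lmm", {
      lm_tab <- res$longit$measures
      rms <- unique(lm_tab[, c("roi", "measure")])
      fits <- do.call(rbind, lapply(seq_len(nrow(rms)), function(i) {
        sub <- lm_tab[lm_tab$roi == rms$roi[i] &
                        lm_tab$measure == rms$measure[i], ]
        cbind(roi = rms$roi[i], measure = rms$measure[i],
              fit_all_groups(sub))
      }))
      fits <- correct_slope_family(fits, q = th$q)
      fits$pattern <- vapply(seq_len(nrow(fits)), function(i)
        classify_pattern(fits[i, ], q = th$q), character(1))
      fits
    })
    wtsv(res$lmm, "lmm/slopes.tsv")
  }

  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res
}
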