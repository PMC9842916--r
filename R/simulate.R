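#' Configuration for a synthetic stroke cohort
#'
#' Bundles every knob of the generator with defaults that emulate the study
#' conditions the package is built to analyse: ellipsoidal subcortical
#' lesions drawn near named loci (two on CST fiber columns, one off-tract
#' "putamen" locus), chronic-stage cortical ROI measures with injected
#' lesion-, fiber- and group-dependent effects, WE_FM motor scores that
#' decrease with M1-fiber impairment and carry a point mass at 100 (so the
#' PR < 100 / CR = 100 dichotomy populates both strata), per-group
#' longitudinal slopes realising the four evolution patterns, and optional
#' 2D measure sheets with group-dependent patches for the cluster-level
#' mapping stages.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param fraction_left probability a patient's lesion is left-hemispheric.
#' @param lesion_size_range lesion volume interval in voxels.
#' @param locus_probs named probabilities over `names(default_loci())` for
#'   the primary lesion locus.
#' @param secondary_lesion list(prob, size_range): each patient
#'   independently carries an additional small lesion at the off-tract
#'   "putamen" locus with probability `prob`. Independence from the primary
#'   (fiber) locus keeps lesion-location effects orthogonal to the fiber
#'   impairments. `prob = 0` disables it.
#' @param effect_table data.frame(trigger, roi, measure, effect,
#'   scale_by_impairment); triggers are `"fiber:<subset>"`,
#'   `"locus:<name>"`, `"group:<PR|CR|HC>"`.
#' @param slope_table data.frame(roi, measure, group, slope) in measure
#'   units per month; missing combinations mean slope 0.
#' @param covariate_effects list with `age` (per year, centred at 55),
#'   `sexM`, and `scanner` (named offsets per scanner level).
#' @param noise_sd residual SD of the measure noise (measure units).
#' @param intercept_sd SD of the per-subject random intercept; the default
#'   equals `noise_sd`, giving an intraclass correlation of about 0.5.
#' @param visit_months nominal visit times (months after stroke), strictly
#'   increasing; a single value gives a cross-sectional cohort.
#' @param visit_jitter uniform relative jitter applied to each visit time.
#' @param wefm_slope WE_FM points lost per percent of M1-fiber impairment.
#' @param wefm_noise SD of the WE_FM noise.
#' @param cr_margin latent WE_FM headroom above 100 for unimpaired
#'   patients; with the default locus mix roughly 45% of patients land at
#'   exactly 100 (complete recovery).
#' @param sheet NULL, or a list(shape, spacing_mm, fwhm_mm, noise_sd,
#'   effects) where effects is data.frame(group, measure, ci, cj, halfwidth,
#'   amplitude) defining square patches added to the sheets of matching
#'   subjects (`group = "patient"` matches PR and CR).
#' @param seed integer seed; all generator randomness derives from it.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_patients = 90L, n_controls = 50L,
                          fraction_left = 0.5,
                          lesion_size_range = c(20L, 120L),
                          locus_probs = c(M1 = 0.35, S1 = 0.3,
                                          capsule = 0.35),
                          secondary_lesion = list(prob = 0.45,
                                                  size_range = c(40L, 90L)),
                          effect_table = default_effect_table(),
                          slope_table = default_slope_table(),
                          covariate_effects = list(
                            age = -0.004, sexM = 0.03,
                            scanner = c(A = 0, B = 0.04, C = -0.04)),
                          noise_sd = 0.15, intercept_sd = noise_sd,
                          visit_months = 12, visit_jitter = 0.2,
                          wefm_slope = 1.2, wefm_noise = 6, cr_margin = 4,
                          sheet = NULL, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              fraction_left = fraction_left,
              lesion_size_range = lesion_size_range,
              locus_probs = locus_probs,
              secondary_lesion = secondary_lesion,
              effect_table = effect_table,
              slope_table = slope_table,
              covariate_effects = covariate_effects,
              noise_sd = noise_sd, intercept_sd = intercept_sd,
              visit_months = visit_months, visit_jitter = visit_jitter,
              wefm_slope = wefm_slope, wefm_noise = wefm_noise,
              cr_margin = cr_margin, sheet = sheet,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1L, cfg$n_controls >= 0L)
  if (cfg$fraction_left < 0 || cfg$fraction_left > 1)
    stop("fraction_left must lie in [0, 1]")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (any(diff(cfg$visit_months) <= 0) && length(cfg$visit_months) > 1L)
    stop("visit_months must be strictly increasing")
  if (abs(sum(cfg$locus_probs) - 1) > 1e-8)
    stop("locus_probs must sum to 1")
  if (cfg$visit_jitter < 0 || cfg$visit_jitter >= 0.5)
    stop("visit_jitter must lie in [0, 0.5)")
  sl <- cfg$secondary_lesion
  if (!is.null(sl) && (sl$prob < 0 || sl$prob > 1))
    stop("secondary_lesion prob must lie in [0, 1]")
  invisible(cfg)
}

#' Default ROI table of the synthetic cohort
#'
#' Ten ipsilesional/contralesional ROI-measure pairs (4 cortical thickness,
#' 3 surface area, 3 gray-matter volume) with baselines in measure units
#' (mm for thickness; the area and volume measures are kept on a comparable
#' numeric scale so one noise_sd applies).
#'
#' @return data.frame with columns `roi`, `measure`, `baseline`.
#' @export
default_roi_table <- function() {
  data.frame(
    roi = c("IL postcentral", "IL frontal pole", "IL precentral",
            "IL lingual", "IL cingulate", "IL temporal pole",
            "IL orbital", "CL rectus", "IL cuneus", "IL lingual gmv"),
    measure = c("thickness", "thickness", "thickness", "thickness",
                "area", "area", "area", "gmv", "gmv", "gmv"),
    baseline = c(2.4, 2.6, 2.5, 2.0, 5.0, 4.6, 4.8, 6.0, 5.6, 5.8),
    stringsAsFactors = FALSE)
}

#' Default injected cross-sectional effects
#'
#' A lesion-locus-coupled surface-area increase in the temporal pole (VLSM
#' target), an M1-fiber-coupled thickness deficit in the precentral ROI, an
#' S1-fiber-coupled thickness increase in the lingual ROI (CST-correlation
#' target), and a PR-only postcentral thickness deficit (ANCOVA target).
#' Fiber-triggered effects scale linearly with the impairment percentage,
#' so the linear impairment covariates of the correlation stage absorb them
#' fully and the family stays specific.
#'
#' @return data.frame(trigger, roi, measure, effect, scale_by_impairment).
#' @export
default_effect_table <- function() {
  data.frame(
    trigger = c("locus:putamen", "fiber:M1", "fiber:S1", "group:PR"),
    roi = c("IL temporal pole", "IL precentral", "IL lingual",
            "IL postcentral"),
    measure = c("area", "thickness", "thickness", "thickness"),
    effect = c(0.45, -0.40, 0.60, -0.30),
    scale_by_impairment = c(FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Default longitudinal slope table (four evolution patterns)
#'
#' Pattern 1 (decline, steeper in PR): IL postcentral thickness.
#' Pattern 2 (increase in both): IL lingual thickness.
#' Pattern 3 (increase only in CR): IL frontal pole thickness.
#' Pattern 4 (divergent): IL cingulate area. Healthy controls are flat;
#' unlisted ROI-group combinations have slope 0.
#'
#' @return data.frame(roi, measure, group, slope) in units/month.
#' @export
default_slope_table <- function() {
  data.frame(
    roi = c("IL postcentral", "IL postcentral",
            "IL lingual", "IL lingual",
            "IL frontal pole", "IL frontal pole",
            "IL cingulate", "IL cingulate"),
    measure = c("thickness", "thickness", "thickness", "thickness",
                "thickness", "thickness", "area", "area"),
    group = c("PR", "CR", "PR", "CR", "PR", "CR", "PR", "CR"),
    slope = c(-0.022, -0.012, 0.030, 0.060, 0.002, 0.025, -0.030, 0.030),
    stringsAsFactors = FALSE)
}

#' Default lesion loci on the toy grid
#'
#' World-mm coordinates (left hemisphere) of the named lesion loci: the
#' M1 and S1 loci sit on the respective fiber columns at mid-column height;
#' the "capsule" and "putamen" loci sit off every column (subcortical
#' lesions that spare the modelled CST fibers). Right-hemisphere lesions
#' mirror x.
#'
#' @param grid a [grid_spec()].
#' @param atlas the matching [make_fiber_atlas()].
#' @return named list of length-3 world coordinates.
#' @export
default_loci <- function(grid, atlas) {
  zmid <- round(grid$shape[3] * 0.6)
  centroid <- function(subset) {
    idx <- which(subset[, , zmid] != 0, arr.ind = TRUE)
    voxel_to_world(grid, cbind(colMeans(idx)[1], colMeans(idx)[2], zmid))
  }
  list(M1 = drop(centroid(atlas$subsets$M1_left)),
       S1 = drop(centroid(atlas$subsets$S1_left)),
       capsule = drop(voxel_to_world(
         grid, cbind(round(grid$shape[1] * 0.125),
                     round(grid$shape[2] * 0.50),
                     round(grid$shape[3] * 0.45)))),
       putamen = drop(voxel_to_world(
         grid, cbind(round(grid$shape[1] * 0.22),
                     round(grid$shape[2] * 0.22),
                     round(grid$shape[3] * 0.45)))))
}

#' Simulate a seeded stroke cohort with known ground truth
#'
#' Draws subjects (patients and healthy controls) with covariates, places
#' an ellipsoidal lesion for each patient near its assigned locus, computes
#' the true CST impairment profile from the lesion and atlas, generates
#' WE_FM scores (decreasing in M1 impairment, truncated at 100 with a point
#' mass there) and the PR/CR/HC grouping, and builds the long measure table
#' across visits: baseline + covariate effects + injected effects +
#' group-specific slope x time + subject random intercept + Gaussian noise.
#' Healthy controls receive covariate effects and noise only. Optionally
#' generates 2D measure sheets with group-dependent patches.
#'
#' If the PR or CR stratum comes out empty, the WE_FM noise is redrawn up
#' to 20 times before failing.
#'
#' @param config a [cohort_config()].
#' @param grid a [grid_spec()].
#' @param atlas a [make_fiber_atlas()] on `grid`.
#' @return list with `subjects` (one row per subject, including true
#'   impairments `imp_*`), `masks` (named list of `lesion_mask`, patients
#'   only), `measures` (long table: subject x ROI x measure x visit),
#'   `sheets` (per measure: list(values, shape, global), or NULL), and
#'   `truth` (generator ground truth: loci, per-subject locus, effect and
#'   slope tables, sheet effects).
#' @export
simulate_cohort <- function(config, grid, atlas) {
  validate_cohort_config(config)
  stopifnot(inherits(grid, "grid_spec"), inherits(atlas, "fiber_atlas"))
  rng <- local_rng(config$seed)
  with_rng(rng, simulate_cohort_impl(config, grid, atlas))
}

simulate_cohort_impl <- function(config, grid, atlas) {
  np <- config$n_patients; nc <- config$n_controls
  n <- np + nc
  loci <- default_loci(grid, atlas)
  subj <- data.frame(
    subject_id = c(sprintf("P%03d", seq_len(np)),
                   if (nc > 0L) sprintf("C%03d", seq_len(nc))),
    is_patient = rep(c(TRUE, FALSE), c(np, nc)),
    age = pmin(75, pmax(30, round(stats::rnorm(n, 55, 8)))),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.7, 0.3)),
    scanner = sample(names(config$covariate_effects$scanner), n,
                     replace = TRUE),
    stringsAsFactors = FALSE)
  subj$hemisphere <- "none"
  subj$hemisphere[subj$is_patient] <-
    ifelse(stats::runif(np) < config$fraction_left, "left", "right")
  subj$locus <- NA_character_
  subj$locus[subj$is_patient] <- sample(names(config$locus_probs), np,
                                        replace = TRUE,
                                        prob = config$locus_probs)

  # lesions: ellipsoid near the assigned locus, mirrored for right lesions;
  # optionally an independent small second lesion at the putamen locus
  masks <- list()
  imp <- matrix(0, nrow = n, ncol = 4,
                dimnames = list(NULL, c("M1", "PMC", "SMA", "S1")))
  subj$lesion_volume <- 0
  subj$has_putamen <- !is.na(subj$locus) & subj$locus == "putamen"
  sl <- config$secondary_lesion
  # world x of every voxel column, for clipping lesions at the midline
  wx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$voxel_size[1]
  draw_lesion <- function(locus_name, hemi, size_range, id) {
    w <- loci[[locus_name]]
    if (hemi == "right") w[1] <- -w[1]
    center <- drop(world_to_voxel(grid, w)) +
      sample(-1L:1L, 3L, replace = TRUE)
    center <- pmin(grid$shape - 1L, pmax(2L, center))
    vol_vox <- stats::runif(1, size_range[1], size_range[2])
    r_mm <- (3 * vol_vox * prod(grid$voxel_size) / (4 * pi))^(1 / 3)
    m <- make_lesion(grid, center, r_mm * stats::runif(3, 0.85, 1.15), id)
    # strokes stay within their hemisphere: clip at the mid-sagittal plane
    m$voxels[if (hemi == "left") wx > 0 else wx < 0, , ] <- 0L
    m
  }
  for (i in which(subj$is_patient)) {
    id <- subj$subject_id[i]
    m <- draw_lesion(subj$locus[i], subj$hemisphere[i],
                     config$lesion_size_range, id)
    if (!is.null(sl) && sl$prob > 0 && stats::runif(1) < sl$prob) {
      m2 <- draw_lesion("putamen", subj$hemisphere[i], sl$size_range, id)
      m <- lesion_mask(grid, m$voxels | m2$voxels, id)
      subj$has_putamen[i] <- TRUE
    }
    masks[[id]] <- m
    subj$lesion_volume[i] <- lesion_volume(m)
    prof <- impairment_profile(m, atlas, subj$hemisphere[i])
    imp[i, prof$subset] <- prof$percentage
  }
  impdf <- as.data.frame(imp)
  names(impdf) <- paste0("imp_", names(impdf))
  subj <- cbind(subj, impdf)

  # WE_FM: latent = 100 + margin - slope * M1 impairment + noise, truncated;
  # the truncation at 100 creates the CR point mass. Redraw noise if a
  # stratum is empty.
  subj$wefm <- NA_real_
  subj$group <- "HC"
  pat <- subj$is_patient
  for (try in seq_len(20L)) {
    latent <- 100 + config$cr_margin -
      config$wefm_slope * subj$imp_M1[pat] +
      stats::rnorm(np, 0, config$wefm_noise)
    wefm <- pmin(100, pmax(0, latent))
    if (any(wefm < 100) && any(wefm == 100)) break
    if (try == 20L) stop("simulate_cohort: could not populate both PR and ",
                         "CR strata; adjust cr_margin/wefm_slope")
  }
  subj$wefm[pat] <- wefm
  subj$group[pat] <- ifelse(wefm < 100, "PR", "CR")

  # visit times with relative jitter (strictly positive nominal times keep
  # their order for jitter < 0.5)
  nv <- length(config$visit_months)
  tmat <- matrix(rep(config$visit_months, each = n), nrow = n) *
    matrix(1 + stats::runif(n * nv, -config$visit_jitter,
                            config$visit_jitter), nrow = n)

  # per-subject random intercept, shared across ROIs of a subject
  b <- stats::rnorm(n, 0, config$intercept_sd)

  roi_tab <- default_roi_table()
  ce <- config$covariate_effects
  cov_term <- ce$age * (subj$age - 55) + ce$sexM * (subj$sex == "M") +
    unname(ce$scanner[subj$scanner])

  eff_term <- matrix(0, nrow = n, ncol = nrow(roi_tab))
  et <- config$effect_table
  for (k in seq_len(nrow(et))) {
    j <- which(roi_tab$roi == et$roi[k] & roi_tab$measure == et$measure[k])
    if (length(j) != 1L) stop("effect_table row ", k, " matches no ROI")
    tr <- strsplit(et$trigger[k], ":", fixed = TRUE)[[1]]
    hit <- switch(tr[1],
      fiber = subj[[paste0("imp_", tr[2])]] > 0,
      locus = if (tr[2] == "putamen") subj$has_putamen else
        !is.na(subj$locus) & subj$locus == tr[2],
      group = subj$group == tr[2],
      stop("unknown trigger type: ", tr[1]))
    scale <- if (isTRUE(et$scale_by_impairment[k]))
      subj[[paste0("imp_", tr[2])]] / 100 else 1
    eff_term[, j] <- eff_term[, j] + et$effect[k] * hit * scale
  }

  slope <- matrix(0, nrow = n, ncol = nrow(roi_tab))
  st <- config$slope_table
  for (k in seq_len(nrow(st))) {
    j <- which(roi_tab$roi == st$roi[k] & roi_tab$measure == st$measure[k])
    if (length(j) != 1L) stop("slope_table row ", k, " matches no ROI")
    slope[subj$group == st$group[k], j] <- st$slope[k]
  }

  rows <- vector("list", nv)
  for (v in seq_len(nv)) {
    tv <- tmat[, v]
    vals <- matrix(rep(roi_tab$baseline, each = n), nrow = n) +
      cov_term + eff_term + slope * tv + b +
      matrix(stats::rnorm(n * nrow(roi_tab), 0, config$noise_sd), nrow = n)
    rows[[v]] <- data.frame(
      subject_id = rep(subj$subject_id, times = nrow(roi_tab)),
      group = rep(subj$group, times = nrow(roi_tab)),
      hemisphere = rep(subj$hemisphere, times = nrow(roi_tab)),
      roi = rep(roi_tab$roi, each = n),
      measure = rep(roi_tab$measure, each = n),
      visit = v,
      timepoint_months = rep(tv, times = nrow(roi_tab)),
      value = as.vector(vals),
      age = rep(subj$age, times = nrow(roi_tab)),
      sex = rep(subj$sex, times = nrow(roi_tab)),
      scanner = rep(subj$scanner, times = nrow(roi_tab)),
      wefm = rep(subj$wefm, times = nrow(roi_tab)),
      lesion_volume = rep(subj$lesion_volume, times = nrow(roi_tab)),
      imp_M1 = rep(subj$imp_M1, times = nrow(roi_tab)),
      imp_PMC = rep(subj$imp_PMC, times = nrow(roi_tab)),
      imp_SMA = rep(subj$imp_SMA, times = nrow(roi_tab)),
      imp_S1 = rep(subj$imp_S1, times = nrow(roi_tab)),
      stringsAsFactors = FALSE)
  }
  measures <- do.call(rbind, rows)

  sheets <- NULL
  if (!is.null(config$sheet))
    sheets <- simulate_sheets(config, subj, cov_term)

  list(subjects = subj, masks = masks, measures = measures, sheets = sheets,
       truth = list(loci = loci, locus = stats::setNames(subj$locus,
                                                         subj$subject_id),
                    has_putamen = stats::setNames(subj$has_putamen,
                                                  subj$subject_id),
                    effect_table = et, slope_table = st,
                    impairments = imp, random_intercepts = b,
                    sheet_effects = config$sheet$effects))
}

# 2D measure sheets: smoothed unit-variance noise * noise_sd + baseline +
# covariate shift + group patches
simulate_sheets <- function(config, subj, cov_term) {
  sc <- config$sheet
  shape <- sc$shape
  sigma_vox <- sc$fwhm_mm / 2.3548 / sc$spacing_mm
  n <- nrow(subj)
  out <- list()
  for (ms in unique(sc$effects$measure)) {
    vals <- matrix(0, nrow = n, ncol = prod(shape))
    eff <- sc$effects[sc$effects$measure == ms, , drop = FALSE]
    for (i in seq_len(n)) {
      z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
      s <- gaussian_smooth_2d(z, sigma_vox)
      s <- s / stats::sd(s) * sc$noise_sd
      fld <- s + cov_term[i]
      for (k in seq_len(nrow(eff))) {
        match_g <- eff$group[k] == subj$group[i] ||
          (eff$group[k] == "patient" && subj$group[i] != "HC")
        if (match_g) {
          ii <- max(1, eff$ci[k] - eff$halfwidth[k]):
            min(shape[1], eff$ci[k] + eff$halfwidth[k])
          jj <- max(1, eff$cj[k] - eff$halfwidth[k]):
            min(shape[2], eff$cj[k] + eff$halfwidth[k])
          fld[ii, jj] <- fld[ii, jj] + eff$amplitude[k]
        }
      }
      vals[i, ] <- as.vector(fld)
    }
    out[[ms]] <- list(values = vals, shape = shape,
                      global = rowMeans(vals))
  }
  out
}

#' Chronic-stage rows of a measure table
#'
#' @param measures the long `measures` table from [simulate_cohort()].
#' @return the rows of the last visit.
#' @export
chronic_table <- function(measures) {
  measures[measures$visit == max(measures$visit), , drop = FALSE]
}
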