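#' Seeded calibration and recovery studies
#'
#' These helpers re-run the package's statistical machinery on freshly
#' generated synthetic cohorts to measure its operating characteristics:
#' false-positive calibration of the VLSM and cluster-correction stages,
#' FDR control of the Benjamini-Yekutieli step, type-I error of the ANCOVA
#' contrasts, confidence-interval coverage of the mixed-model slope, and
#' recovery of injected effects. Every function is deterministic in `seed`.
#'
#' @name calibration
NULL

# cross-sectional lesion cohort with no lesion-outcome coupling
null_lesion_cohort <- function(n, grid, atlas, seed) {
  cc <- cohort_config(n_patients = n, n_controls = 0, fraction_left = 1,
                      effect_table = default_effect_table()[0, ],
                      slope_table = default_slope_table()[0, ],
                      seed = seed)
  simulate_cohort(cc, grid, atlas)
}

#' VLSM false-positive calibration under the null
#'
#' Generates cohorts whose chronic outcome is independent of lesion
#' anatomy, runs [vlsm_map()] with the standard covariates, and returns the
#' mean fraction of tested voxels surviving voxel-level FDR.
#'
#' @param n_reps number of null cohorts.
#' @param n patients per cohort.
#' @param seed integer seed.
#' @return list with `mean_fraction` and `n_reps`.
#' @export
eval_vlsm_null <- function(n_reps = 200L, n = 60L, seed = 1L) {
  grid <- grid_spec()
  atlas <- make_fiber_atlas(grid, seed)
  fracs <- vapply(seq_len(n_reps), function(r) {
    co <- null_lesion_cohort(n, grid, atlas, seed + r)
    tab <- chronic_table(co$measures)
    sub <- tab[tab$roi == "IL orbital", ]   # no injected coupling anywhere
    res <- vlsm_map(co$masks, sub$value,
                    sub[, c("age", "sex", "scanner", "lesion_volume")])
    if (res$n_tested == 0L) return(0)
    sum(res$q_field <= 0.05, na.rm = TRUE) / res$n_tested
  }, numeric(1))
  list(mean_fraction = mean(fracs), n_reps = n_reps)
}

#' VLSM localisation of an injected lesion-locus effect
#'
#' Injects a one-standard-deviation ("d = 1") outcome shift in patients
#' lesioned at the off-tract locus and measures how often the largest
#' reported cluster's centroid falls within `tol_vox` voxels of the true
#' locus.
#'
#' @param n_reps replicates.
#' @param n patients per cohort.
#' @param tol_vox tolerance in voxels.
#' @param seed integer seed.
#' @return list with `success_rate`, `n_reps`.
#' @export
eval_vlsm_recovery <- function(n_reps = 50L, n = 120L, tol_vox = 2,
                               seed = 1L) {
  grid <- grid_spec()
  atlas <- make_fiber_atlas(grid, seed)
  sd_total <- sqrt(0.15^2 + 0.15^2)   # generator noise + intercept SD
  eff <- data.frame(trigger = "locus:putamen", roi = "IL temporal pole",
                    measure = "area", effect = sd_total,
                    scale_by_impairment = FALSE)
  hits <- vapply(seq_len(n_reps), function(r) {
    cc <- cohort_config(n_patients = n, n_controls = 0, fraction_left = 1,
                        locus_probs = c(M1 = 0.3, S1 = 0.2, putamen = 0.5),
                        secondary_lesion = list(prob = 0, size_range = c(40L, 90L)),
                        effect_table = eff,
                        slope_table = default_slope_table()[0, ],
                        seed = seed + r)
    co <- simulate_cohort(cc, grid, atlas)
    tab <- chronic_table(co$measures)
    sub <- tab[tab$roi == "IL temporal pole", ]
    res <- vlsm_map(co$masks, sub$value,
                    sub[, c("age", "sex", "scanner", "lesion_volume")])
    pos <- res$clusters[res$clusters$sign > 0, , drop = FALSE]
    if (nrow(pos) == 0L) return(FALSE)
    main <- pos[which.max(pos$n_voxels), ]
    d <- sqrt(sum((unlist(main[c("center_x", "center_y", "center_z")]) -
                     co$truth$loci$putamen)^2)) / grid$voxel_size[1]
    d <= tol_vox
  }, logical(1))
  list(success_rate = mean(hits), n_reps = n_reps)
}

#' Familywise error of the Monte-Carlo cluster correction
#'
#' Generates null two-group sheet cohorts whose subject fields follow the
#' generator's noise model (white noise smoothed to the analysis FWHM),
#' applies the full pointwise-GLM + cluster-extent pipeline, and returns
#' the fraction of cohorts with any surviving cluster.
#'
#' @param n_reps null cohorts.
#' @param n_per_group subjects per group.
#' @param shape sheet dimensions.
#' @param n_sims null simulations for the extent distribution.
#' @param seed integer seed.
#' @return list with `fwer`, `n_reps`.
#' @export
eval_mc_fwer <- function(n_reps = 200L, n_per_group = 40L,
                         shape = c(64L, 64L), n_sims = 500L, seed = 1L) {
  n <- 2L * n_per_group
  sigma_vox <- 10 / 2.3548 / 2
  rng <- local_rng(seed)
  gen <- function() t(vapply(seq_len(n), function(i) {
    z <- with_rng(rng, matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
    s <- gaussian_smooth_2d(z, sigma_vox)
    as.vector(s / stats::sd(s))
  }, numeric(prod(shape))))
  design0 <- with_rng(rng, data.frame(
    group = factor(rep(c("HC", "patient"), each = n_per_group),
                   levels = c("HC", "patient")),
    age = stats::rnorm(n, 55, 8),
    sex = sample(c("M", "F"), n, TRUE)))
  null_ext <- simulate_null_max_extents(shape, voxel_p = 0.01,
                                        fwhm_mm = 10, spacing_mm = 2,
                                        n_sims = n_sims, seed = seed + 1L)
  any_hit <- vapply(seq_len(n_reps), function(r) {
    vals <- gen()
    design <- design0
    design$global <- rowMeans(vals)
    st <- fit_pointwise_glm(vals, shape, design)
    st <- monte_carlo_cluster_correct(st, voxel_p = 0.01,
                                      cluster_alpha = 0.05,
                                      null_extents = null_ext)
    any(st$clusters$retained)
  }, logical(1))
  list(fwer = mean(any_hit), n_reps = n_reps)
}

#' Empirical FDR of the BY procedure under independent nulls
#'
#' @param n_reps repetitions.
#' @param m p-values per repetition (all null, uniform).
#' @param q nominal rate.
#' @param seed integer seed.
#' @return list with `fdr` (mean false-discovery proportion), `n_reps`.
#' @export
eval_by_fdr_null <- function(n_reps = 2000L, m = 50L, q = 0.05, seed = 1L) {
  rng <- local_rng(seed)
  fdp <- vapply(seq_len(n_reps), function(r) {
    p <- with_rng(rng, stats::runif(m))
    rej <- by_fdr(p, q)$reject
    if (any(rej)) 1 else 0   # all hypotheses null: FDP is 0 or 1
  }, numeric(1))
  list(fdr = mean(fdp), n_reps = n_reps)
}

#' Type-I error of the covariate-adjusted ANCOVA contrasts
#'
#' Three groups drawn from one distribution with covariate effects only;
#' returns the rejection rate of each pairwise contrast at alpha = .05.
#'
#' @param n_reps simulated data sets.
#' @param n_per_group subjects per group.
#' @param seed integer seed.
#' @return list with `rate` (mean over the three contrasts), `per_pair`,
#'   `n_reps`.
#' @export
eval_ancova_type1 <- function(n_reps = 1000L, n_per_group = 25L, seed = 1L) {
  rng <- local_rng(seed)
  group <- rep(c("PR", "CR", "HC"), each = n_per_group)
  n <- length(group)
  rej <- matrix(NA, n_reps, 3L)
  for (r in seq_len(n_reps)) {
    res <- with_rng(rng, {
      age <- stats::rnorm(n, 55, 8)
      scanner <- sample(c("A", "B", "C"), n, TRUE)
      value <- -0.004 * (age - 55) + c(A = 0, B = 0.04, C = -0.04)[scanner] +
        stats::rnorm(n, 0, 0.15)
      ancova_three_group(value, group,
                         data.frame(age = age, scanner = scanner))
    })
    rej[r, ] <- res$p < 0.05
  }
  list(rate = mean(rej), per_pair = colMeans(rej), n_reps = n_reps)
}

#' Coverage of the mixed-model slope confidence interval
#'
#' Balanced cohorts at the generator's variance defaults; the Wald 95%
#' interval for the slope is checked against the true value.
#'
#' @param n_reps simulated cohorts.
#' @param n_subj subjects per cohort.
#' @param times visit times (months).
#' @param slope true slope (units/month).
#' @param seed integer seed.
#' @return list with `coverage`, `n_reps`.
#' @export
eval_lmm_coverage <- function(n_reps = 300L, n_subj = 40L,
                              times = c(0.25, 1, 3, 7), slope = 0.02,
                              seed = 1L) {
  rng <- local_rng(seed)
  covered <- vapply(seq_len(n_reps), function(r) {
    d <- with_rng(rng, {
      b <- stats::rnorm(n_subj, 0, 0.15)
      data.frame(
        subject_id = rep(sprintf("S%03d", seq_len(n_subj)),
                         each = length(times)),
        timepoint_months = rep(times, n_subj),
        value = 2 + slope * rep(times, n_subj) +
          rep(b, each = length(times)) +
          stats::rnorm(n_subj * length(times), 0, 0.15))
    })
    f <- fit_random_intercept(d)
    abs(f$beta1 - slope) <= stats::qnorm(0.975) * f$se1
  }, logical(1))
  list(coverage = mean(covered), n_reps = n_reps)
}

#' Classification rate of the divergent-trajectories pattern
#'
#' Simulates longitudinal cohorts at generator defaults and reports how
#' often the ROI carrying the divergent (pattern 4) slopes is labelled "4".
#'
#' @param n_reps simulated cohorts.
#' @param seed integer seed.
#' @return list with `rate`, `n_reps`, and the label table of the four
#'   designated pattern ROIs over replicates.
#' @export
eval_pattern_classification <- function(n_reps = 50L, seed = 1L) {
  grid <- grid_spec()
  atlas <- make_fiber_atlas(grid, seed)
  targets <- c("IL postcentral" = "1", "IL lingual" = "2",
               "IL frontal pole" = "3", "IL cingulate" = "4")
  labs <- matrix(NA_character_, n_reps, length(targets),
                 dimnames = list(NULL, names(targets)))
  for (r in seq_len(n_reps)) {
    cc <- cohort_config(n_patients = 80, n_controls = 12,
                        visit_months = c(0.25, 1, 3, 7), seed = seed + r)
    co <- simulate_cohort(cc, grid, atlas)
    rms <- unique(co$measures[, c("roi", "measure")])
    fits <- do.call(rbind, lapply(seq_len(nrow(rms)), function(i) {
      sub <- co$measures[co$measures$roi == rms$roi[i] &
                           co$measures$measure == rms$measure[i], ]
      cbind(roi = rms$roi[i], fit_all_groups(sub))
    }))
    fits <- correct_slope_family(fits, q = 0.05)
    for (roi in names(targets))
      labs[r, roi] <- classify_pattern(fits[fits$roi == roi, ], q = 0.05)
  }
  list(rate = mean(labs[, "IL cingulate"] == "4"),
       per_roi = vapply(names(targets),
                        function(roi) mean(labs[, roi] == targets[roi]),
                        numeric(1)),
       n_reps = n_reps)
}
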