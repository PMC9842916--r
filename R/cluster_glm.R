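#' Pointwise group-difference GLM over measure sheets
#'
#' Mass-univariate ordinary least squares at every point of a 2D measure
#' sheet (a flat stand-in for a surface hemisphere): value ~ group +
#' covariates. Covariates conventionally include age, sex, scanner, and the
#' measure-matched whole-cortex global value. Returns the t and two-sided p
#' field for the group coefficient.
#'
#' @param values numeric matrix, subjects x points (sheets flattened
#'   column-major).
#' @param shape integer pair, the sheet dimensions; `prod(shape)` must equal
#'   `ncol(values)`.
#' @param design data.frame of per-subject covariates, including the group
#'   column; factors are dummy-coded via [stats::model.matrix()].
#' @param group_col name of the design column whose coefficient is tested
#'   (a two-level factor or 0/1 indicator).
#' @return A `stat_map`: list with `t`, `p` (matrices of shape `shape`),
#'   `df`, `shape`, and `clusters = NULL` until corrected.
#' @export
fit_pointwise_glm <- function(values, shape, design, group_col = "group") {
  stopifnot(is.matrix(values), length(shape) == 2L,
            prod(shape) == ncol(values), nrow(values) == nrow(design))
  if (!group_col %in% names(design))
    stop("design has no column '", group_col, "'")
  mm <- stats::model.matrix(~ ., data = design)
  qx <- qr(mm)
  if (qx$rank < ncol(mm)) {
    bad <- colnames(mm)[qx$pivot[(qx$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(mm) <= ncol(mm) + 2L)
    stop("too few subjects for the design: n = ", nrow(mm),
         ", rank = ", ncol(mm))
  gi <- which(attr(mm, "assign") == match(group_col, names(design)))
  if (length(gi) != 1L)
    stop("group column '", group_col, "' must contribute exactly one ",
         "coefficient (two-level factor or 0/1 indicator)")
  xtxi <- chol2inv(chol(crossprod(mm)))
  beta <- xtxi %*% crossprod(mm, values)
  res <- values - mm %*% beta
  df <- nrow(mm) - ncol(mm)
  sigma2 <- colSums(res^2) / df
  tval <- beta[gi, ] / sqrt(pmax(sigma2, .Machine$double.eps) * xtxi[gi, gi])
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(t = matrix(tval, shape[1], shape[2]),
                 p = matrix(pval, shape[1], shape[2]),
                 df = df, shape = as.integer(shape), clusters = NULL),
            class = "stat_map")
}

#' Null distribution of the maximum suprathreshold cluster extent
#'
#' Simulates Gaussian white-noise sheets, smooths them to the requested
#' full-width-at-half-maximum, standardises every point exactly to unit
#' variance (the smoothing weights give the pointwise variance in closed
#' form, including at the edges), thresholds the field two-sidedly at the
#' quantile whose exceedance probability is `voxel_p` — the same exceedance
#' rate the observed t-field has at its own `voxel_p` threshold — and
#' records the largest sign-specific 4-connected component over both signs.
#'
#' @param shape integer pair, sheet dimensions.
#' @param voxel_p voxelwise two-sided threshold (e.g. 0.01).
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param spacing_mm sheet point spacing in mm.
#' @param n_sims number of simulated null fields (>= 100).
#' @param seed integer seed.
#' @return integer vector of length `n_sims` of maximum extents.
#' @export
simulate_null_max_extents <- function(shape, voxel_p = 0.01,
                                      fwhm_mm = 10, spacing_mm = 2,
                                      n_sims = 1000L, seed = 1L) {
  if (n_sims < 100L) stop("n_sims must be >= 100")
  sigma_vox <- fwhm_mm / 2.3548 / spacing_mm
  smooth <- sigma_vox >= 0.3
  if (fwhm_mm < spacing_mm)
    warning("smoothing FWHM below one sheet spacing; fields left unsmoothed")
  if (smooth) {
    kx <- smoothing_band(shape[1], sigma_vox)
    ky <- smoothing_band(shape[2], sigma_vox)
    sdmap <- outer(sqrt(rowSums(kx^2)), sqrt(rowSums(ky^2)))
  }
  zcrit <- stats::qnorm(1 - voxel_p / 2)
  rng <- local_rng(seed)
  vapply(seq_len(n_sims), function(i) {
    z <- with_rng(rng, matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
    s <- if (smooth) (kx %*% z %*% t(ky)) / sdmap else z
    max_extent_two_sided(s, zcrit)
  }, integer(1))
}

max_extent_two_sided <- function(field, tcrit) {
  best <- 0L
  for (mk in list(field > tcrit, field < -tcrit)) {
    if (any(mk)) {
      lab <- label_components(mk)
      best <- max(best, max(tabulate(lab[lab > 0L])))
    }
  }
  best
}

#' Monte-Carlo cluster-extent correction of a stat map
#'
#' Thresholds the observed t field voxelwise (two-sided `voxel_p`,
#' sign-specific 4-connected clustering) and assigns each cluster an extent
#' p-value against the simulated null distribution of the maximum
#' suprathreshold extent, using the (1 + k) / (n_sims + 1) estimator.
#' Clusters with `cluster_p <= cluster_alpha` are retained.
#'
#' @param stat a `stat_map` from [fit_pointwise_glm()].
#' @param n_sims number of null simulations (ignored when `null_extents`
#'   is supplied).
#' @param voxel_p voxelwise two-sided threshold.
#' @param cluster_alpha cluster-level retention threshold.
#' @param fwhm_mm,spacing_mm smoothing geometry for the null fields.
#' @param seed integer seed for the null simulation.
#' @param null_extents optional precomputed vector from
#'   [simulate_null_max_extents()] (must match `df`, `voxel_p`, geometry).
#' @return the `stat_map` with `clusters` (data.frame: id, sign, size,
#'   cluster_p, peak/center indices, retained flag) and `cluster_indices`
#'   (list of point-index matrices for retained clusters) filled in.
#' @export
monte_carlo_cluster_correct <- function(stat, n_sims = 1000L, voxel_p = 0.01,
                                        cluster_alpha = 0.05, fwhm_mm = 10,
                                        spacing_mm = 2, seed = 1L,
                                        null_extents = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  if (is.null(null_extents))
    null_extents <- simulate_null_max_extents(stat$shape, voxel_p,
                                              fwhm_mm, spacing_mm,
                                              n_sims, seed)
  n_sims <- length(null_extents)
  tcrit <- stats::qt(1 - voxel_p / 2, stat$df)
  rows <- list(); indices <- list(); id <- 0L
  for (sgn in c(1, -1)) {
    mk <- if (sgn > 0) stat$t > tcrit else stat$t < -tcrit
    if (!any(mk)) next
    lab <- label_components(mk)
    for (k in seq_len(max(lab))) {
      cs <- cluster_stats(lab, stat$t, k)
      id <- id + 1L
      cp <- (1 + sum(null_extents >= cs$size)) / (n_sims + 1)
      rows[[id]] <- data.frame(
        id = id, sign = sgn, size = cs$size, cluster_p = cp,
        peak_i = cs$peak[1], peak_j = cs$peak[2], peak_t = cs$peak_value,
        center_i = cs$center[1], center_j = cs$center[2],
        retained = cp <= cluster_alpha)
      indices[[id]] <- cs$indices
    }
  }
  if (id == 0L) {
    stat$clusters <- data.frame(id = integer(), sign = numeric(),
                                size = integer(), cluster_p = numeric(),
                                peak_i = numeric(), peak_j = numeric(),
                                peak_t = numeric(), center_i = numeric(),
                                center_j = numeric(), retained = logical())
    stat$cluster_indices <- list()
    return(stat)
  }
  stat$clusters <- do.call(rbind, rows)
  stat$cluster_indices <- indices[stat$clusters$retained]
  names(stat$cluster_indices) <-
    as.character(stat$clusters$id[stat$clusters$retained])
  stat
}

#' Confirm discovery clusters in an independent replication sample
#'
#' Within each retained discovery cluster (seed mask), the group GLM is
#' refit on the replication sample; replication points with p below `alpha`
#' and t of the same sign as the discovery cluster peak survive. A cluster
#' is confirmed as a region of interest when at least one point survives.
#'
#' @param discovery a corrected `stat_map` (with `cluster_indices`).
#' @param rep_values,rep_shape,rep_design,group_col replication sample, as
#'   in [fit_pointwise_glm()]; `rep_shape` must equal the discovery shape.
#' @param alpha replication pointwise threshold (default 0.05).
#' @return list of ROIs, each a list with `name`, `indices` (point-index
#'   matrix of surviving points), `sign`, `seed_size`, `n_points`.
#' @export
replicate_rois <- function(discovery, rep_values, rep_shape, rep_design,
                           group_col = "group", alpha = 0.05) {
  stopifnot(inherits(discovery, "stat_map"),
            all(rep_shape == discovery$shape))
  if (length(discovery$cluster_indices) == 0L) return(list())
  rep_stat <- fit_pointwise_glm(rep_values, rep_shape, rep_design, group_col)
  keep <- discovery$clusters[discovery$clusters$retained, , drop = FALSE]
  rois <- list()
  for (r in seq_len(nrow(keep))) {
    idx <- discovery$cluster_indices[[as.character(keep$id[r])]]
    pv <- rep_stat$p[idx]
    tv <- rep_stat$t[idx]
    ok <- pv < alpha & sign(tv) == keep$sign[r]
    if (!any(ok)) next
    rois[[length(rois) + 1L]] <- list(
      name = sprintf("cluster%02d_%s", keep$id[r],
                     if (keep$sign[r] > 0) "pos" else "neg"),
      indices = idx[ok, , drop = FALSE],
      sign = keep$sign[r],
      seed_size = keep$size[r],
      n_points = sum(ok))
  }
  rois
}

#' Per-subject mean of a sheet measure over an ROI
#'
#' @param roi an ROI from [replicate_rois()] (or any list with an `indices`
#'   point-index matrix).
#' @param values subjects x points matrix, same layout as in
#'   [fit_pointwise_glm()].
#' @param shape sheet dimensions.
#' @return numeric vector, one mean per subject.
#' @export
roi_summary <- function(roi, values, shape) {
  idx <- roi$indices
  if (is.null(idx) || nrow(idx) == 0L) stop("roi_summary: empty ROI")
  lin <- (idx[, 2] - 1L) * shape[1] + idx[, 1]
  rowMeans(values[, lin, drop = FALSE])
}
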