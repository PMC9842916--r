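#' Voxel inclusion mask for lesion-symptom mapping
#'
#' A voxel is tested only when it is damaged in strictly more than
#' `fraction` of the patients (e.g. exactly 10% of patients does not pass a
#' 0.10 threshold).
#'
#' @param masks list of `lesion_mask` objects on a common grid.
#' @param fraction minimum damaged fraction (strict inequality), default 0.10.
#' @return logical 3D array.
#' @export
build_inclusion_mask <- function(masks, fraction = 0.10) {
  inc <- incidence_map(masks)
  inc$counts / inc$n_subjects > fraction
}

#' Continuous-outcome voxel-based lesion-symptom mapping
#'
#' At every included voxel, fits outcome ~ lesion_status(0/1) + covariates
#' by ordinary least squares and tests the lesion coefficient (two-sided).
#' Voxelwise multiple comparisons are corrected with a voxel-level FDR
#' procedure (Benjamini-Hochberg by default); surviving voxels are
#' decomposed into 6-connected clusters and clusters with strictly more than
#' `min_cluster` voxels are reported with their unweighted centroid and
#' max-|t| peak in world mm.
#'
#' Voxels lesioned in every subject carry no contrast; they are skipped with
#' a warning.
#'
#' @param masks list of `lesion_mask` objects (one hemisphere lesion group).
#' @param outcome numeric vector, one chronic-stage ROI measure per subject,
#'   aligned with `masks`.
#' @param covariates data.frame of per-subject nuisance variables
#'   (conventionally age, sex, scanner, lesion volume).
#' @param min_incidence strict inclusion fraction (default 0.10).
#' @param min_cluster strict minimum cluster voxel count (default 10).
#' @param q voxel-level FDR (default 0.05).
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @return A `vlsm_result`: list with `grid`, `tested` (logical array),
#'   `t_field`, `p_field`, `q_field` (arrays, `NA` outside tested voxels),
#'   `n_tested`, and `clusters` (data.frame: id, sign, n_voxels, volume_mm3,
#'   center/peak world mm, peak_t).
#' @export
vlsm_map <- function(masks, outcome, covariates, min_incidence = 0.10,
                     min_cluster = 10L, q = 0.05, fdr_method = c("BH", "BY")) {
  fdr_method <- match.arg(fdr_method)
  n <- length(masks)
  stopifnot(length(outcome) == n)
  grid <- masks[[1]]$grid
  tested <- build_inclusion_mask(masks, min_incidence)
  cm <- covariate_matrix(covariates, n)
  if (n < qr(cbind(1, cm))$rank + 3L) stop("vlsm_map: too few subjects")
  lin <- which(tested)
  if (length(lin) > 0L) {
    L <- vapply(masks, function(m) m$voxels[lin], numeric(length(lin)))
    L <- if (length(lin) == 1L) matrix(L, nrow = 1L) else L  # voxels x n
    full <- rowSums(L) == n
    if (any(full)) {
      warning(sum(full), " voxel(s) lesioned in all subjects skipped ",
              "(no contrast)")
      tested[lin[full]] <- FALSE
      lin <- lin[!full]
      L <- L[!full, , drop = FALSE]
    }
  }
  t_field <- p_field <- q_field <- array(NA_real_, dim = grid$shape)
  clusters <- data.frame(id = integer(), sign = numeric(),
                         n_voxels = integer(), volume_mm3 = numeric(),
                         center_x = numeric(), center_y = numeric(),
                         center_z = numeric(), peak_x = numeric(),
                         peak_y = numeric(), peak_z = numeric(),
                         peak_t = numeric())
  res <- structure(list(grid = grid, tested = tested, t_field = t_field,
                        p_field = p_field, q_field = q_field,
                        n_tested = length(lin), clusters = clusters),
                   class = "vlsm_result")
  if (length(lin) == 0L) return(res)
  # residualise outcome and every voxel's lesion indicator on the covariates;
  # the partial-correlation t equals the OLS t for the lesion coefficient
  X0 <- cbind(1, cm)
  k <- ncol(cm)
  hat <- X0 %*% chol2inv(chol(crossprod(X0))) %*% t(X0)
  ry <- outcome - hat %*% outcome
  RL <- t(L) - hat %*% t(L)                     # n x voxels
  sy <- sqrt(sum(ry^2))
  sl <- sqrt(colSums(RL^2))
  r <- drop(crossprod(RL, ry)) / pmax(sl * sy, .Machine$double.eps)
  r <- pmin(1 - 1e-12, pmax(-1 + 1e-12, r))
  df <- n - 2L - k
  tv <- r * sqrt(df / (1 - r^2))
  pv <- 2 * stats::pt(-abs(tv), df)
  qv <- if (fdr_method == "BH") stats::p.adjust(pv, "BH") else
    by_fdr(pv, q)$corrected
  res$t_field[lin] <- tv
  res$p_field[lin] <- pv
  res$q_field[lin] <- qv
  surv <- array(FALSE, dim = grid$shape)
  surv[lin[qv <= q]] <- TRUE
  if (!any(surv)) return(res)
  lab <- label_components(surv)
  rows <- list()
  for (cid in seq_len(max(lab))) {
    cs <- cluster_stats(lab, ifelse(is.na(res$t_field), 0, res$t_field), cid)
    if (cs$size <= min_cluster) next
    cw <- voxel_to_world(grid, cs$center)
    pw <- voxel_to_world(grid, cs$peak)
    rows[[length(rows) + 1L]] <- data.frame(
      id = length(rows) + 1L, sign = sign(cs$peak_value),
      n_voxels = cs$size,
      volume_mm3 = cs$size * prod(grid$voxel_size),
      center_x = cw[1], center_y = cw[2], center_z = cw[3],
      peak_x = pw[1], peak_y = pw[2], peak_z = pw[3],
      peak_t = cs$peak_value)
  }
  if (length(rows) > 0L) res$clusters <- do.call(rbind, rows)
  res
}

#' VLSM over a batch of ROI-measure outcomes
#'
#' One independent [vlsm_map()] per (ROI, measure) pair; FDR correction is
#' within-map.
#'
#' @param masks list of `lesion_mask` objects with `subject_id` set.
#' @param table chronic-stage measure table (patients matching `masks`):
#'   columns `subject_id`, `roi`, `measure`, `value`, `age`, `sex`,
#'   `scanner`, `lesion_volume`.
#' @param roi_measures data.frame with columns `roi`, `measure`; empty
#'   input gives an empty list.
#' @param ... passed to [vlsm_map()].
#' @return named list of `vlsm_result` (names `"roi|measure"`).
#' @export
vlsm_batch <- function(masks, table, roi_measures, ...) {
  out <- list()
  if (nrow(roi_measures) == 0L) return(out)
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  for (i in seq_len(nrow(roi_measures))) {
    sub <- table[table$roi == roi_measures$roi[i] &
                   table$measure == roi_measures$measure[i], ]
    sub <- sub[match(ids, sub$subject_id), ]
    if (any(is.na(sub$value)))
      stop("vlsm_batch: missing outcome for some subjects at ",
           roi_measures$roi[i])
    covs <- sub[, c("age", "sex", "scanner", "lesion_volume")]
    out[[paste(roi_measures$roi[i], roi_measures$measure[i], sep = "|")]] <-
      vlsm_map(masks, sub$value, covs, ...)
  }
  out
}
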