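#' Benjamini-Yekutieli false-discovery-rate step-up procedure
#'
#' Valid under arbitrary dependence between tests. With m sorted p-values
#' p(1) <= ... <= p(m) and harmonic factor c(m) = sum_{j=1..m} 1/j, the
#' largest i with p(i) <= i * q / (m * c(m)) and all smaller ranks are
#' rejected. Corrected p-values are p(i) * m * c(m) / i with monotonicity
#' enforced from the largest rank down and capped at 1; rejection at level q
#' is equivalent to corrected p <= q.
#'
#' @param raw_ps numeric vector of p-values in (0, 1].
#' @param q target false-discovery rate (default 0.05).
#' @return list with `corrected` (same order as input) and `reject`
#'   (logical). Empty input returns empty vectors.
#' @export
by_fdr <- function(raw_ps, q = 0.05) {
  if (length(raw_ps) == 0L)
    return(list(corrected = numeric(0), reject = logical(0)))
  if (any(!is.finite(raw_ps)) || any(raw_ps <= 0) || any(raw_ps > 1))
    stop("by_fdr: p-values must lie in (0, 1]")
  m <- length(raw_ps)
  cm <- sum(1 / seq_len(m))
  ord <- order(raw_ps)
  ps <- raw_ps[ord]
  adj <- ps * m * cm / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(adj))))
  corrected <- numeric(m)
  corrected[ord] <- adj
  # step-up rejection on the raw scale (equivalent to corrected <= q)
  thresh <- seq_len(m) * q / (m * cm)
  below <- which(ps <= thresh)
  reject <- logical(m)
  if (length(below) > 0L) reject[ord[seq_len(max(below))]] <- TRUE
  list(corrected = corrected, reject = reject)
}

#' Cohen's d between two groups
#'
#' (mean_a - mean_b) / pooled SD, pooling variances with (n_a - 1, n_b - 1)
#' weights.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return the standardised mean difference.
#' @export
cohens_d <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("cohens_d: each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("cohens_d: zero pooled standard deviation")
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}

# dummy-code a covariate set (data.frame or matrix) without an intercept,
# rejecting collinear columns
covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), nrow = n, ncol = 0L))
  cm <- if (is.data.frame(covariates))
    stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  else as.matrix(covariates)
  if (nrow(cm) != n) stop("covariates have wrong length")
  if (ncol(cm) > 0L) {
    r <- qr(cbind(1, cm))
    if (r$rank < ncol(cm) + 1L) {
      bad <- colnames(cbind(`(Intercept)` = 1, cm))[r$pivot[(r$rank + 1L):(ncol(cm) + 1L)]]
      stop("collinear covariate columns: ", paste(bad, collapse = ", "))
    }
  }
  cm
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the residuals of `x` and `y` after ordinary
#' least-squares regression on the covariates (plus intercept). The p-value
#' comes from t = pr * sqrt(df / (1 - pr^2)) with df = n - 2 - k, k the
#' number of dummy-coded covariate columns. With no covariates this is the
#' plain Pearson correlation test.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional data.frame (factors allowed) or numeric matrix.
#' @return list with `pr`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  cm <- covariate_matrix(covariates, n)
  k <- ncol(cm)
  if (n <= k + 3L) stop("partial_correlation: need n > k + 3")
  xm <- cbind(1, cm)
  rx <- stats::lm.fit(xm, x)$residuals
  ry <- stats::lm.fit(xm, y)$residuals
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop("partial_correlation: constant residuals")
  pr <- stats::cor(rx, ry)
  df <- n - 2L - k
  tt <- pr * sqrt(df / max(1 - pr^2, .Machine$double.eps))
  list(pr = pr, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Three-group ANCOVA with pairwise covariate-adjusted contrasts
#'
#' Fits value ~ group + covariates by ordinary least squares and reports the
#' three pairwise group contrasts (PR-CR, PR-HC, CR-HC) with two-sided
#' p-values on the residual degrees of freedom. Cohen's d is computed on the
#' covariate-adjusted scale by default (contrast estimate divided by the
#' model residual SD, so d matches the ANCOVA contrast); `adjusted_d =
#' FALSE` gives the raw-value pooled-SD d instead.
#'
#' @param values numeric outcome vector.
#' @param group factor/character with levels among PR, CR, HC; every group
#'   present needs >= 3 subjects.
#' @param covariates optional data.frame or matrix (age, sex, scanner,
#'   matched global measure, ...).
#' @param adjusted_d logical, see above.
#' @return data.frame with one row per pair: `pair`, `estimate`, `se`, `t`,
#'   `df`, `p`, `d`.
#' @export
ancova_three_group <- function(values, group, covariates = NULL,
                               adjusted_d = TRUE) {
  group <- factor(as.character(group), levels = c("PR", "CR", "HC"))
  if (any(is.na(group))) stop("group labels must be PR, CR or HC")
  tab <- table(group)
  if (any(tab < 3L))
    stop("each group needs >= 3 subjects; counts: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  n <- length(values)
  cm <- covariate_matrix(covariates, n)
  gm <- stats::model.matrix(~ group)[, -1L, drop = FALSE]  # CR, HC vs PR
  X <- cbind(1, gm, cm)
  fit <- stats::lm.fit(X, values)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  xtxi <- chol2inv(chol(crossprod(X)))
  # coefficient positions: 2 = groupCR (CR - PR), 3 = groupHC (HC - PR)
  contrasts <- list("PR-CR" = c(0, -1, 0), "PR-HC" = c(0, 0, -1),
                    "CR-HC" = c(0, 1, -1))
  out <- lapply(names(contrasts), function(nm) {
    L <- c(contrasts[[nm]], rep(0, ncol(cm)))
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% xtxi %*% L) * sigma2)
    tt <- est / se
    ab <- strsplit(nm, "-")[[1]]
    d <- if (adjusted_d) est / sqrt(sigma2) else
      cohens_d(values[group == ab[1]], values[group == ab[2]])
    data.frame(pair = nm, estimate = est, se = se, t = tt, df = df,
               p = 2 * stats::pt(-abs(tt), df), d = d)
  })
  do.call(rbind, out)
}

#' Partial correlations between ROI measures and motor outcome
#'
#' For each (ROI, measure) pair, the partial correlation between the ROI
#' value and the WE_FM score controlling for age, sex and scanner, with
#' Benjamini-Yekutieli correction over the whole family.
#'
#' @param table chronic-stage measure table (patients only): data.frame with
#'   columns `roi`, `measure`, `value`, `wefm`, `age`, `sex`, `scanner`,
#'   `subject_id`.
#' @param roi_measures data.frame with columns `roi`, `measure` defining the
#'   family (defaults to all combinations present).
#' @param q false-discovery rate.
#' @return data.frame: `roi`, `measure`, `pr`, `df`, `raw_p`, `corrected_p`,
#'   `reject`.
#' @export
wefm_correlations <- function(table, roi_measures = NULL, q = 0.05) {
  if (is.null(roi_measures))
    roi_measures <- unique(table[, c("roi", "measure")])
  rows <- lapply(seq_len(nrow(roi_measures)), function(i) {
    sub <- table[table$roi == roi_measures$roi[i] &
                   table$measure == roi_measures$measure[i], ]
    pc <- partial_correlation(sub$value, sub$wefm,
                              sub[, c("age", "sex", "scanner")])
    data.frame(roi = roi_measures$roi[i], measure = roi_measures$measure[i],
               pr = pc$pr, df = pc$df, raw_p = pc$p)
  })
  res <- do.call(rbind, rows)
  fdr <- by_fdr(res$raw_p, q)
  res$corrected_p <- fdr$corrected
  res$reject <- fdr$reject
  res
}

#' Partial correlations between CST-subset impairment and ROI measures
#'
#' For each (ROI, measure) pair and each fiber subset s in {M1, PMC, SMA,
#' S1}: the partial correlation between the subset's impairment percentage
#' and the ROI value, controlling for age, sex, scanner and the other three
#' subsets' impairment percentages. Benjamini-Yekutieli correction is
#' applied across the whole family (#pairs x 4 tests). Subsets whose
#' impairment is zero for every subject are reported as not testable
#' (`NA` statistics) rather than raising an error.
#'
#' @param table chronic-stage measure table restricted to one hemisphere
#'   lesion group, patients only; columns as in [wefm_correlations()] plus
#'   `imp_M1`, `imp_PMC`, `imp_SMA`, `imp_S1`.
#' @param roi_measures data.frame with columns `roi`, `measure` (defaults to
#'   all combinations present).
#' @param q false-discovery rate.
#' @return data.frame: `roi`, `measure`, `subset`, `pr`, `df`, `raw_p`,
#'   `corrected_p`, `reject`, `testable`.
#' @export
cst_correlations <- function(table, roi_measures = NULL, q = 0.05) {
  if (any(table$group == "HC"))
    stop("cst_correlations: patients only (controls have no lesion)")
  if (is.null(roi_measures))
    roi_measures <- unique(table[, c("roi", "measure")])
  subsets <- c("M1", "PMC", "SMA", "S1")
  rows <- list()
  for (i in seq_len(nrow(roi_measures))) {
    sub <- table[table$roi == roi_measures$roi[i] &
                   table$measure == roi_measures$measure[i], ]
    for (s in subsets) {
      xcol <- paste0("imp_", s)
      others <- paste0("imp_", setdiff(subsets, s))
      row <- data.frame(roi = roi_measures$roi[i],
                        measure = roi_measures$measure[i], subset = s,
                        pr = NA_real_, df = NA_real_, raw_p = NA_real_,
                        testable = FALSE)
      if (stats::sd(sub[[xcol]]) > 0) {
        covs <- sub[, c("age", "sex", "scanner"), drop = FALSE]
        for (oc in others)  # drop degenerate all-constant nuisance subsets
          if (stats::sd(sub[[oc]]) > 0) covs[[oc]] <- sub[[oc]]
        pc <- partial_correlation(sub[[xcol]], sub$value, covs)
        row$pr <- pc$pr; row$df <- pc$df; row$raw_p <- pc$p
        row$testable <- TRUE
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  res$corrected_p <- NA_real_
  res$reject <- NA
  ok <- res$testable
  if (any(ok)) {
    fdr <- by_fdr(res$raw_p[ok], q)
    res$corrected_p[ok] <- fdr$corrected
    res$reject[ok] <- fdr$reject
  }
  res
}
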