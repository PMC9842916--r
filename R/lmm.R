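#' Random-intercept linear mixed model by REML
#'
#' Fits y_ij = b0 + b1 * t_ij + u_i + e_ij with u_i ~ N(0, sigma2_b) and
#' e_ij ~ N(0, sigma2_e) for one group of subjects, by restricted maximum
#' likelihood. The common slope is a fixed effect; only intercepts vary by
#' subject, which absorbs the correlation between repeated measurements.
#' Subjects with missing visits contribute the visits they have.
#'
#' The likelihood is profiled down to the variance ratio gamma =
#' sigma2_b / sigma2_e and optimised on the log-gamma scale (tolerance
#' 1e-10), with the gamma = 0 boundary checked explicitly; block closed
#' forms make each evaluation exact. The slope test is a Wald z test.
#'
#' @param data data.frame of one group's observations.
#' @param value_col,time_col,subject_col column names (defaults `value`,
#'   `timepoint_months`, `subject_id`).
#' @return list with `beta0`, `beta1`, `se0`, `se1`, `p_slope` (Wald,
#'   normal reference), `sigma2_b`, `sigma2_e`, `logreml`, `gamma`,
#'   `n_subjects`, `n_obs`, `converged`.
#' @export
fit_random_intercept <- function(data, value_col = "value",
                                 time_col = "timepoint_months",
                                 subject_col = "subject_id") {
  y <- as.numeric(data[[value_col]])
  t <- as.numeric(data[[time_col]])
  subj <- factor(data[[subject_col]])
  ok <- is.finite(y) & is.finite(t)
  y <- y[ok]; t <- t[ok]; subj <- droplevels(subj[ok])
  n_subj <- nlevels(subj)
  if (n_subj < 3L) stop("fit_random_intercept: need >= 3 subjects")
  if (length(unique(t)) < 2L) stop("fit_random_intercept: need >= 2 distinct times")
  X <- cbind(1, t)
  N <- length(y); p <- 2L
  si <- split(seq_len(N), subj)
  ni <- lengths(si)

  # GLS pieces for a given variance ratio gamma (V = sigma2_e (I + gamma ZZ'))
  gls <- function(gamma) {
    # W = (I + gamma ZZ')^{-1} applied via per-subject rank-one downdates
    shrink <- gamma / (1 + gamma * ni)
    wapply <- function(M) {
      out <- M
      for (k in seq_along(si)) {
        r <- si[[k]]
        out[r, ] <- M[r, , drop = FALSE] -
          shrink[k] * rep(colSums(M[r, , drop = FALSE]), each = ni[k])
      }
      out
    }
    WX <- wapply(X)
    Wy <- wapply(matrix(y))
    XtWX <- crossprod(X, WX)
    beta <- solve(XtWX, crossprod(X, Wy))
    r <- y - X %*% beta
    rWr <- sum(r * wapply(r))
    list(beta = drop(beta), XtWX = XtWX, rWr = rWr,
         logdetV0 = sum(log1p(gamma * ni)))
  }
  # profiled -2 restricted log-likelihood (up to an additive constant)
  obj <- function(loggamma) {
    g <- gls(exp(loggamma))
    (N - p) * log(max(g$rWr, 1e-300)) + g$logdetV0 +
      determinant(g$XtWX, logarithm = TRUE)$modulus[1]
  }
  g0 <- gls(0)
  if (g0$rWr < 1e-12 * max(1, sum(y^2))) {
    # degenerate noiseless fit: exact line through every observation
    return(list(beta0 = unname(g0$beta[1]), beta1 = unname(g0$beta[2]),
                se0 = 0, se1 = 0,
                p_slope = NA_real_, sigma2_b = 0, sigma2_e = 0,
                logreml = Inf, gamma = 0, n_subjects = n_subj, n_obs = N,
                converged = TRUE))
  }
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-10)
  crit0 <- (N - p) * log(g0$rWr) + determinant(g0$XtWX, TRUE)$modulus[1]
  if (crit0 <= opt$objective) {
    gamma <- 0; best <- g0; crit <- crit0
  } else {
    gamma <- exp(opt$minimum); best <- gls(gamma); crit <- opt$objective
  }
  sigma2_e <- best$rWr / (N - p)
  sigma2_b <- gamma * sigma2_e
  covb <- solve(best$XtWX) * sigma2_e
  se <- unname(sqrt(diag(covb)))
  beta <- unname(best$beta)
  z <- beta[2] / se[2]
  loglik <- -0.5 * (crit + (N - p) * (1 + log(2 * pi) - log(N - p)))
  list(beta0 = beta[1], beta1 = beta[2],
       se0 = se[1], se1 = se[2],
       p_slope = 2 * stats::pnorm(-abs(z)),
       sigma2_b = sigma2_b, sigma2_e = sigma2_e,
       logreml = loglik, gamma = gamma,
       n_subjects = n_subj, n_obs = N, converged = TRUE)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML criterion of the random-intercept model at arbitrary
#' (sigma2_b, sigma2_e), with the fixed effects set to their GLS estimates
#' at those variances. Used to verify that [fit_random_intercept()] returns
#' a (local) optimum.
#'
#' @inheritParams fit_random_intercept
#' @param sigma2_b,sigma2_e variance components (sigma2_e > 0).
#' @return the restricted log-likelihood (including constants).
#' @export
reml_loglik <- function(data, sigma2_b, sigma2_e, value_col = "value",
                        time_col = "timepoint_months",
                        subject_col = "subject_id") {
  stopifnot(sigma2_e > 0, sigma2_b >= 0)
  y <- as.numeric(data[[value_col]])
  t <- as.numeric(data[[time_col]])
  subj <- factor(data[[subject_col]])
  X <- cbind(1, t)
  N <- length(y); p <- 2L
  gamma <- sigma2_b / sigma2_e
  si <- split(seq_len(N), subj)
  ni <- lengths(si)
  shrink <- gamma / (1 + gamma * ni)
  wapply <- function(M) {
    out <- M
    for (k in seq_along(si)) {
      r <- si[[k]]
      out[r, ] <- M[r, , drop = FALSE] -
        shrink[k] * rep(colSums(M[r, , drop = FALSE]), each = ni[k])
    }
    out
  }
  WX <- wapply(X)
  XtWX <- crossprod(X, WX)
  beta <- solve(XtWX, crossprod(X, wapply(matrix(y))))
  r <- y - X %*% beta
  rWr <- sum(r * wapply(r))
  logdetV <- N * log(sigma2_e) + sum(log1p(gamma * ni))
  logdetXVX <- determinant(XtWX / sigma2_e, TRUE)$modulus[1]
  -0.5 * (logdetV + logdetXVX + rWr / sigma2_e + (N - p) * log(2 * pi))
}

#' Fit the three recovery groups and compare their slopes
#'
#' Fits [fit_random_intercept()] separately for the PR, CR and HC groups of
#' one ROI-measure series and tests every pairwise slope difference with a
#' Wald combination z = (b1_a - b1_b) / sqrt(se_a^2 + se_b^2) against the
#' normal reference.
#'
#' @param data long data.frame with columns `group` (PR/CR/HC), `value`,
#'   `timepoint_months`, `subject_id`.
#' @return one-row data.frame: per-group `slope_*`, `se_*`, `p_*` and
#'   pairwise `diff_*`, `p_*vs*` columns.
#' @export
fit_all_groups <- function(data) {
  groups <- c("PR", "CR", "HC")
  fits <- lapply(groups, function(g)
    fit_random_intercept(data[data$group == g, , drop = FALSE]))
  names(fits) <- groups
  out <- data.frame(row.names = NULL,
                    slope_PR = fits$PR$beta1, se_PR = fits$PR$se1, p_PR = fits$PR$p_slope,
                    slope_CR = fits$CR$beta1, se_CR = fits$CR$se1, p_CR = fits$CR$p_slope,
                    slope_HC = fits$HC$beta1, se_HC = fits$HC$se1, p_HC = fits$HC$p_slope)
  pairs <- list(PRvsCR = c("PR", "CR"), CRvsHC = c("CR", "HC"),
                PRvsHC = c("PR", "HC"))
  for (nm in names(pairs)) {
    a <- fits[[pairs[[nm]][1]]]; b <- fits[[pairs[[nm]][2]]]
    z <- (a$beta1 - b$beta1) / sqrt(a$se1^2 + b$se1^2)
    out[[paste0("diff_", nm)]] <- a$beta1 - b$beta1
    out[[paste0("p_", nm)]] <- 2 * stats::pnorm(-abs(z))
  }
  attr(out, "fits") <- fits
  out
}

#' Benjamini-Yekutieli correction of the slope families
#'
#' Applies [by_fdr()] across the slope-significance family (all ROIs x 3
#' groups) and, separately, across the pairwise slope-difference family (all
#' ROIs x 3 pairs), mirroring the two corrected families of the longitudinal
#' analysis.
#'
#' @param fits data.frame with one row per ROI-measure, stacked
#'   [fit_all_groups()] rows plus identifying columns.
#' @param q false-discovery rate.
#' @return `fits` with `q_PR`, `q_CR`, `q_HC`, `q_PRvsCR`, `q_CRvsHC`,
#'   `q_PRvsHC` columns added.
#' @export
correct_slope_family <- function(fits, q = 0.05) {
  stopifnot(nrow(fits) >= 1L)
  slope_cols <- c("p_PR", "p_CR", "p_HC")
  diff_cols <- c("p_PRvsCR", "p_CRvsHC", "p_PRvsHC")
  for (cols in list(slope_cols, diff_cols)) {
    raw <- unlist(fits[, cols], use.names = FALSE)
    corr <- rep(NA_real_, length(raw))
    ok <- !is.na(raw)
    if (any(ok)) corr[ok] <- by_fdr(raw[ok], q)$corrected
    cm <- matrix(corr, nrow = nrow(fits))
    for (j in seq_along(cols))
      fits[[sub("^p_", "q_", cols[j])]] <- cm[, j]
  }
  fits
}

#' Classify the longitudinal evolution pattern of one ROI
#'
#' Rule-based labels on BY-corrected significance at level `q`:
#' pattern 4 = divergent trajectories (significant PR-vs-CR slope
#' difference, opposite slope signs, and both patient slopes individually
#' significant); pattern 1 = both patient slopes negative with a
#' significant PR decline; pattern 2 = both patient slopes positive and
#' both significant; pattern 3 = significant CR increase without a
#' significant PR change; `"none"` otherwise. Rules are checked in the
#' order 4, 1, 2, 3.
#'
#' @param fit one row of a [correct_slope_family()] result.
#' @param q significance level on corrected p-values.
#' @return one of `"1"`, `"2"`, `"3"`, `"4"`, `"none"`.
#' @export
classify_pattern <- function(fit, q = 0.05) {
  sig <- function(col) !is.na(fit[[col]]) && fit[[col]] <= q
  spr <- fit$slope_PR; scr <- fit$slope_CR
  if (sig("q_PRvsCR") && sign(spr) != sign(scr) && spr != 0 && scr != 0 &&
      sig("q_PR") && sig("q_CR"))
    return("4")
  if (spr < 0 && scr < 0 && sig("q_PR")) return("1")
  if (spr > 0 && scr > 0 && sig("q_PR") && sig("q_CR")) return("2")
  if (scr > 0 && sig("q_CR") && !sig("q_PR")) return("3")
  "none"
}
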