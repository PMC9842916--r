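make_lmm_data <- function(n_subj, times, slope, intercept = 2,
                          sigma_b = 0.3, sigma_e = 0.2, seed = 1,
                          group = NULL) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subj), function(i) {
    b <- rnorm(1, 0, sigma_b)
    data.frame(subject_id = sprintf("S%03d", i),
               group = if (is.null(group)) NA_character_ else group,
               timepoint_months = times,
               value = intercept + slope * times + b +
                 rnorm(length(times), 0, sigma_e))
  }))
}

test_that("a noiseless shared line is fit exactly with zero variances", {
  d <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3),
                  timepoint_months = rep(c(0, 1, 2), 3))
  d$value <- 2 + 0.5 * d$timepoint_months
  f <- fit_random_intercept(d)
  expect_identical(f$beta0, 2)
  expect_identical(f$beta1, 0.5)
  expect_identical(f$sigma2_b, 0)
  expect_identical(f$sigma2_e, 0)
})

test_that("REML matches the closed-form balanced ANOVA estimators to 1e-6", {
  times <- c(0, 1, 3, 7)
  d <- make_lmm_data(40, times, slope = 0.05, seed = 81)
  f <- fit_random_intercept(d)
  ymat <- matrix(d$value, nrow = length(times))
  o <- oracle_balanced_reml(ymat, times)
  expect_equal(f$beta0, o$beta0, tolerance = 1e-6)
  expect_equal(f$beta1, o$beta1, tolerance = 1e-6)
  expect_equal(f$sigma2_e, o$sigma2_e, tolerance = 1e-6)
  expect_equal(f$sigma2_b, o$sigma2_b, tolerance = 1e-6)
})

test_that("REML agrees with lme4 on unbalanced data", {
  set.seed(82)
  d <- do.call(rbind, lapply(1:25, function(i) {
    ti <- sort(runif(sample(2:4, 1), 0, 8))
    data.frame(subject_id = sprintf("S%02d", i), timepoint_months = ti,
               value = 1.5 + 0.08 * ti + rnorm(1, 0, 0.25) +
                 rnorm(length(ti), 0, 0.15))
  }))
  f <- fit_random_intercept(d)
  m <- lme4::lmer(value ~ timepoint_months + (1 | subject_id), d,
                  REML = TRUE)
  expect_equal(f$beta1, unname(lme4::fixef(m)[2]), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(f$sigma2_b, vc$vcov[1], tolerance = 1e-5)
  expect_equal(f$sigma2_e, vc$vcov[2], tolerance = 1e-5)
  expect_equal(f$se1, sqrt(as.matrix(vcov(m))[2, 2]), tolerance = 1e-5)
  expect_equal(f$logreml, as.numeric(stats::logLik(m)), tolerance = 1e-6)
})

test_that("zero between-subject variance reduces the fit to OLS", {
  set.seed(83)
  d <- make_lmm_data(20, c(0, 2, 5), slope = 0.2, sigma_b = 0, sigma_e = 1,
                     seed = 83)
  f <- fit_random_intercept(d)
  o <- lm(value ~ timepoint_months, d)
  if (f$gamma == 0) {
    expect_equal(f$beta0, unname(coef(o)[1]), tolerance = 1e-8)
    expect_equal(f$beta1, unname(coef(o)[2]), tolerance = 1e-8)
  } else {
    # tiny estimated gamma: coefficients still OLS-close
    expect_equal(f$beta1, unname(coef(o)[2]), tolerance = 1e-3)
  }
})

test_that("the returned estimate is a local REML optimum", {
  d <- make_lmm_data(30, c(0, 1, 3, 7), slope = 0.03, seed = 84)
  f <- fit_random_intercept(d)
  base <- reml_loglik(d, f$sigma2_b, f$sigma2_e)
  expect_equal(base, f$logreml, tolerance = 1e-6)
  set.seed(85)
  for (i in 1:50) {
    s2b <- max(0, f$sigma2_b * exp(rnorm(1, 0, 0.5)))
    s2e <- f$sigma2_e * exp(rnorm(1, 0, 0.5))
    expect_lte(reml_loglik(d, s2b, s2e), base + 1e-8)
  }
})

test_that("slope statistics are equivariant to time rescaling", {
  d <- make_lmm_data(25, c(0, 1, 3, 7), slope = 0.04, seed = 86)
  f1 <- fit_random_intercept(d)
  d2 <- transform(d, timepoint_months = timepoint_months * 30)  # days
  f2 <- fit_random_intercept(d2)
  expect_equal(f2$beta1 * 30, f1$beta1, tolerance = 1e-6)
  expect_equal(f2$p_slope, f1$p_slope, tolerance = 1e-6)
})

test_that("per-subject constant shifts are absorbed by the random intercept", {
  d <- make_lmm_data(30, c(0, 1, 3, 7), slope = 0.03, sigma_b = 0.2,
                     seed = 87)
  f1 <- fit_random_intercept(d)
  shift <- rnorm(30, 0, 0.1)
  d2 <- d
  d2$value <- d2$value + shift[as.integer(factor(d2$subject_id))]
  f2 <- fit_random_intercept(d2)
  expect_equal(f2$beta1, f1$beta1, tolerance = 0.01)
})

test_that("group fits and slope contrasts assemble into one row", {
  d <- rbind(
    transform(make_lmm_data(20, c(0, 1, 3, 7), -0.05, seed = 88),
              group = "PR", subject_id = paste0("PR", subject_id)),
    transform(make_lmm_data(25, c(0, 1, 3, 7), 0.05, seed = 89),
              group = "CR", subject_id = paste0("CR", subject_id)),
    transform(make_lmm_data(10, c(0, 1, 3, 7), 0, seed = 90),
              group = "HC", subject_id = paste0("HC", subject_id)))
  row <- fit_all_groups(d)
  expect_lt(row$slope_PR, 0)
  expect_gt(row$slope_CR, 0)
  expect_lt(row$p_PRvsCR, 0.001)
  fits <- attr(row, "fits")
  z <- (fits$PR$beta1 - fits$CR$beta1) /
    sqrt(fits$PR$se1^2 + fits$CR$se1^2)
  expect_equal(row$p_PRvsCR, 2 * pnorm(-abs(z)))
})

test_that("family correction matches by_fdr and single tests stay raw", {
  fits <- data.frame(p_PR = c(0.001, 0.2), p_CR = c(0.03, 0.5),
                     p_HC = c(0.9, 0.7), p_PRvsCR = c(0.004, 0.6),
                     p_CRvsHC = c(0.02, 0.8), p_PRvsHC = c(0.5, 0.9))
  out <- correct_slope_family(fits, q = 0.05)
  slopes <- unlist(fits[, c("p_PR", "p_CR", "p_HC")], use.names = FALSE)
  expect_equal(unlist(out[, c("q_PR", "q_CR", "q_HC")], use.names = FALSE),
               by_fdr(slopes, 0.05)$corrected)
  one <- correct_slope_family(fits[1, ][, 1:6, drop = FALSE], q = 0.05)
  # families of three: corrected = p * 3 * c(3) / rank, never below raw
  expect_true(all(one$q_PR >= one$p_PR))
})

test_that("pattern rules label constructed fits as specified", {
  row <- function(spr, scr, qpr, qcr, qdiff)
    data.frame(slope_PR = spr, slope_CR = scr, slope_HC = 0,
               q_PR = qpr, q_CR = qcr, q_HC = 1,
               q_PRvsCR = qdiff, q_CRvsHC = 1, q_PRvsHC = 1)
  expect_identical(classify_pattern(row(-0.02, -0.005, 0.01, 0.4, 0.4)), "1")
  expect_identical(classify_pattern(row(0.03, 0.06, 0.01, 0.001, 0.3)), "2")
  expect_identical(classify_pattern(row(0.002, 0.02, 0.6, 0.01, 0.4)), "3")
  expect_identical(classify_pattern(row(-0.02, 0.02, 0.01, 0.01, 0.001)), "4")
  expect_identical(classify_pattern(row(-0.02, 0.02, 0.2, 0.2, 0.2)), "none")
})
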