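# shared toy sheet cohort: smoothed unit-variance noise per subject
make_sheet_cohort <- function(n_pat, n_hc, shape = c(24L, 24L), seed = 1) {
  set.seed(seed)
  n <- n_pat + n_hc
  sig <- 10 / 2.3548 / 2
  vals <- t(vapply(seq_len(n), function(i) {
    z <- gaussian_smooth_2d(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                            sig)
    as.vector(z / sd(z))
  }, numeric(prod(shape))))
  design <- data.frame(
    group = factor(rep(c("HC", "patient"), c(n_hc, n_pat)),
                   levels = c("HC", "patient")),
    age = rnorm(n, 55, 8),
    sex = sample(c("M", "F"), n, TRUE),
    global = rowMeans(vals))
  list(values = vals, shape = shape, design = design)
}

test_that("pointwise GLM reproduces per-point lm and its invariances", {
  co <- make_sheet_cohort(15, 15, seed = 2)
  st <- fit_pointwise_glm(co$values, co$shape, co$design)
  for (j in c(1, 57, 200, prod(co$shape))) {
    fit <- lm(co$values[, j] ~ group + age + sex + global, data = co$design)
    expect_equal(as.vector(st$t)[j],
                 summary(fit)$coefficients["grouppatient", "t value"],
                 tolerance = 1e-10)
  }
  expect_equal(st$df, 30 - 5)
  # adding a constant to every sheet is absorbed by the intercept
  st2 <- fit_pointwise_glm(co$values + 5, co$shape,
                           transform(co$design, global = global + 5))
  expect_equal(st2$t, st$t, tolerance = 1e-9)
  # subject order is irrelevant
  perm <- sample(nrow(co$values))
  st3 <- fit_pointwise_glm(co$values[perm, ], co$shape, co$design[perm, ])
  expect_equal(st3$t, st$t, tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  co <- make_sheet_cohort(10, 10, seed = 3)
  co$design$age2 <- co$design$age
  expect_error(fit_pointwise_glm(co$values, co$shape, co$design), "age2")
})

test_that("null cohorts give ~5% voxelwise false positives", {
  co <- make_sheet_cohort(60, 60, shape = c(64L, 64L), seed = 4)
  st <- fit_pointwise_glm(co$values, co$shape, co$design)
  frac <- mean(st$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("an injected patch dominates the t field and survives correction", {
  co <- make_sheet_cohort(30, 30, shape = c(32L, 32L), seed = 5)
  pat <- co$design$group == "patient"
  idx <- as.vector(outer(1:32 %in% 12:17, 1:32 %in% 12:17)) > 0
  co$values[pat, idx] <- co$values[pat, idx] + 1.2
  st <- fit_pointwise_glm(co$values, co$shape, co$design)
  peak <- which(st$t == max(st$t), arr.ind = TRUE)
  expect_true(all(peak[1, ] >= 12 & peak[1, ] <= 17))
  st <- monte_carlo_cluster_correct(st, n_sims = 200, seed = 6)
  kept <- st$clusters[st$clusters$retained, ]
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$sign, 1)
  expect_true(kept$center_i >= 12 && kept$center_i <= 17)
  # a vanishing voxel threshold leaves nothing suprathreshold
  st0 <- monte_carlo_cluster_correct(fit_pointwise_glm(co$values, co$shape,
                                                       co$design),
                                     voxel_p = 1e-12, n_sims = 200, seed = 6)
  expect_identical(nrow(st0$clusters), 0L)
})

test_that("cluster p-values use the (1+k)/(N+1) estimator against the null", {
  co <- make_sheet_cohort(25, 25, shape = c(32L, 32L), seed = 8)
  st <- fit_pointwise_glm(co$values, co$shape, co$design)
  null_ext <- simulate_null_max_extents(c(32L, 32L), n_sims = 150, seed = 9)
  st <- monte_carlo_cluster_correct(st, null_extents = null_ext)
  if (nrow(st$clusters) > 0) {
    expected <- (1 + vapply(st$clusters$size,
                            function(s) sum(null_ext >= s), numeric(1))) /
      (length(null_ext) + 1)
    expect_equal(st$clusters$cluster_p, expected)
  }
  expect_true(all(st$clusters$cluster_p > 0))
})

test_that("replication confirms injected effects and rejects removed ones", {
  disc <- make_sheet_cohort(40, 40, shape = c(32L, 32L), seed = 10)
  idx <- as.vector(outer(1:32 %in% 10:16, 1:32 %in% 10:16)) > 0
  pat <- disc$design$group == "patient"
  disc$values[pat, idx] <- disc$values[pat, idx] + 1.2
  st <- fit_pointwise_glm(disc$values, disc$shape, disc$design)
  st <- monte_carlo_cluster_correct(st, n_sims = 200, seed = 11)
  expect_gte(length(st$cluster_indices), 1L)
  # replication with the same injected effect: ROI confirmed at the locus
  rep1 <- make_sheet_cohort(40, 40, shape = c(32L, 32L), seed = 12)
  pat1 <- rep1$design$group == "patient"
  rep1$values[pat1, idx] <- rep1$values[pat1, idx] + 1.2
  rois <- replicate_rois(st, rep1$values, rep1$shape, rep1$design)
  expect_gte(length(rois), 1L)
  ci <- mean(rois[[1]]$indices[, 1])
  expect_true(ci >= 10 && ci <= 16)
  # replication without the effect: at most scattered alpha-level survivors
  rep0 <- make_sheet_cohort(40, 40, shape = c(32L, 32L), seed = 13)
  rois0 <- replicate_rois(st, rep0$values, rep0$shape, rep0$design)
  n0 <- if (length(rois0)) sum(vapply(rois0, `[[`, numeric(1), "n_points"))
        else 0
  expect_lt(n0, sum(vapply(rois, `[[`, numeric(1), "n_points")))
  # empty seed set: empty ROI list
  st_empty <- monte_carlo_cluster_correct(
    fit_pointwise_glm(rep0$values, rep0$shape, rep0$design),
    voxel_p = 1e-10, n_sims = 200, seed = 14)
  expect_identical(replicate_rois(st_empty, rep1$values, rep1$shape,
                                  rep1$design), list())
})

test_that("roi_summary averages exactly over the ROI points", {
  vals <- matrix(seq_len(5 * 12), nrow = 5)
  shape <- c(3L, 4L)
  roi <- list(indices = cbind(c(1L, 3L, 2L), c(1L, 2L, 4L)))
  lin <- (roi$indices[, 2] - 1L) * 3L + roi$indices[, 1]
  brute <- apply(vals[, lin], 1, mean)
  expect_equal(roi_summary(roi, vals, shape), brute)
  const <- matrix(2.5, nrow = 4, ncol = 12)
  expect_equal(roi_summary(roi, const, shape), rep(2.5, 4))
  single <- list(indices = cbind(2L, 3L))
  expect_equal(roi_summary(single, vals, shape), vals[, (3 - 1) * 3 + 2])
})
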