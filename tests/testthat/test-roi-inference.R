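test_that("BY step-up matches its worked cases exactly", {
  # m = 1: c(1) = 1, reduces to the raw threshold
  r1 <- by_fdr(0.04, q = 0.05)
  expect_true(r1$reject)
  expect_equal(r1$corrected, 0.04)
  # m = 4, c(4) = 25/12: thresholds i * .05 / (4 * 25/12) = i * 0.006
  r4 <- by_fdr(c(0.001, 0.01, 0.02, 0.2), q = 0.05)
  expect_identical(r4$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r4$corrected[1], 0.001 * 4 * (25 / 12) / 1)
  # corrected p-values are monotone in the sorted order
  expect_true(all(diff(r4$corrected[order(c(0.001, 0.01, 0.02, 0.2))]) >= 0))
  expect_error(by_fdr(c(0.5, 0)), "0, 1")
  expect_identical(by_fdr(numeric(0))$reject, logical(0))
})

test_that("BY agrees with the brute-force oracle and p.adjust on random input", {
  set.seed(51)
  for (i in 1:200) {
    m <- sample(1:40, 1)
    p <- pmin(1, pmax(1e-12, c(runif(m) * rbinom(m, 1, 0.7) + 1e-6)))
    q <- sample(c(0.01, 0.05, 0.1), 1)
    mine <- by_fdr(p, q)
    expect_identical(mine$reject, oracle_by(p, q))
    expect_equal(mine$corrected, p.adjust(p, "BY"))
    # BY never rejects where BH does not
    bh <- p.adjust(p, "BH") <= q
    expect_true(all(!mine$reject | bh))
    expect_true(all(mine$corrected >= p))
  }
})

test_that("Cohen's d matches closed forms and the pooled formula", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(52)
  a <- rnorm(40, 1, 1); b <- rnorm(60, 0, 1)
  sp <- sqrt(((39) * var(a) + (59) * var(b)) / 98)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("partial correlation matches oracles to 1e-10", {
  set.seed(53)
  n <- 80
  z <- matrix(rnorm(n * 3), n, 3)
  x <- z %*% c(1, -0.5, 0.2) + rnorm(n)
  y <- 0.4 * x + z %*% c(-1, 0.3, 0.5) + rnorm(n)
  mine <- partial_correlation(x, y, z)
  expect_equal(mine$pr, oracle_partial_r(x, y, z), tolerance = 1e-10)
  expect_equal(mine$df, n - 2 - 3)
  # no covariates: plain Pearson
  plain <- partial_correlation(x, y)
  expect_equal(plain$pr, drop(cor(x, y)))
  expect_equal(plain$p, cor.test(as.numeric(x), as.numeric(y))$p.value,
               tolerance = 1e-10)
  # noise-free linear relation net of the confounder: pr -> 1
  y1 <- x + z[, 1] * 2
  expect_gt(partial_correlation(x, y1, z)$pr, 1 - 1e-8)
  # duplicated covariate columns are collinear
  expect_error(partial_correlation(x, y, cbind(z, z[, 1])), "collinear")
  expect_error(partial_correlation(x, rep(1, n), z), "constant")
})

test_that("ANCOVA recovers adjusted contrasts and is order invariant", {
  set.seed(54)
  n <- c(PR = 40, CR = 50, HC = 60)
  group <- rep(names(n), n)
  age <- rnorm(sum(n), 55, 8)
  scanner <- sample(c("A", "B"), sum(n), TRUE)
  truth <- c(PR = -0.3, CR = 0, HC = 0)
  value <- truth[group] - 0.01 * (age - 55) + 0.05 * (scanner == "B") +
    rnorm(sum(n), 0, 0.1)
  covs <- data.frame(age = age, scanner = scanner)
  res <- ancova_three_group(value, group, covs)
  expect_setequal(res$pair, c("PR-CR", "PR-HC", "CR-HC"))
  expect_lt(abs(res$estimate[res$pair == "PR-HC"] - (-0.3)), 0.05)
  expect_lt(abs(res$estimate[res$pair == "CR-HC"]), 0.05)
  expect_lt(res$p[res$pair == "PR-HC"], 0.001)
  # adjusted d equals the contrast over the ANCOVA residual SD
  fit <- lm(value ~ factor(group, levels = c("PR", "CR", "HC")) + age +
              scanner)
  sigma_hat <- sqrt(sum(fit$residuals^2) / fit$df.residual)
  expect_equal(res$d, res$estimate / sigma_hat, tolerance = 1e-8)
  # raw-value d falls back to the pooled-SD formula
  raw <- ancova_three_group(value, group, covs, adjusted_d = FALSE)
  expect_equal(raw$d[raw$pair == "PR-HC"],
               cohens_d(value[group == "PR"], value[group == "HC"]))
  perm <- sample(sum(n))
  res2 <- ancova_three_group(value[perm], group[perm], covs[perm, ])
  expect_equal(res2$estimate, res$estimate, tolerance = 1e-10)
  expect_equal(res2$p, res$p, tolerance = 1e-10)
  expect_error(ancova_three_group(value[1:45], group[1:45], covs[1:45, ]),
               ">= 3")
})

test_that("ANCOVA matches lm contrasts coefficient by coefficient", {
  set.seed(55)
  n <- 90
  group <- sample(c("PR", "CR", "HC"), n, TRUE)
  value <- rnorm(n)
  age <- rnorm(n)
  res <- ancova_three_group(value, group, data.frame(age = age))
  fit <- lm(value ~ g + age,
            data = data.frame(g = factor(group, c("PR", "CR", "HC")),
                              age = age))
  expect_equal(res$estimate[res$pair == "PR-CR"], -coef(fit)[["gCR"]],
               tolerance = 1e-12)
  expect_equal(res$estimate[res$pair == "PR-HC"], -coef(fit)[["gHC"]],
               tolerance = 1e-12)
  expect_equal(res$estimate[res$pair == "CR-HC"],
               coef(fit)[["gCR"]] - coef(fit)[["gHC"]], tolerance = 1e-12)
  sm <- summary(fit)$coefficients
  expect_equal(res$p[res$pair == "PR-CR"], sm["gCR", "Pr(>|t|)"],
               tolerance = 1e-12)
})

test_that("CST correlation family flags only the injected subset coupling", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  eff <- data.frame(trigger = "fiber:S1", roi = "IL lingual",
                    measure = "thickness", effect = 0.8,
                    scale_by_impairment = TRUE)
  cc <- cohort_config(n_patients = 120, n_controls = 0,
                      locus_probs = c(M1 = 0.35, S1 = 0.35, putamen = 0.3),
                      effect_table = eff,
                      slope_table = default_slope_table()[0, ],
                      noise_sd = 0.08, intercept_sd = 0.08, seed = 61)
  co <- simulate_cohort(cc, g, a)
  tab <- chronic_table(co$measures)
  res <- cst_correlations(tab, q = 0.05)
  hit <- res[res$roi == "IL lingual" & res$measure == "thickness" &
               res$subset == "S1", ]
  expect_true(hit$reject)
  expect_gt(hit$pr, 0.3)
  others <- res[!(res$roi == "IL lingual" & res$subset == "S1") &
                  res$testable, ]
  expect_true(all(!others$reject))
  expect_error(cst_correlations(transform(tab, group = "HC")), "patients")
})
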