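test_that("cohort generation is deterministic and leaves the global RNG alone", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  cc <- cohort_config(n_patients = 20, n_controls = 10, seed = 42)
  set.seed(999); before <- runif(1)
  co1 <- simulate_cohort(cc, g, a)
  co2 <- simulate_cohort(cc, g, a)
  expect_identical(co1$measures, co2$measures)
  expect_identical(co1$subjects, co2$subjects)
  set.seed(999)
  expect_identical(runif(1), before)
  co3 <- simulate_cohort(cohort_config(n_patients = 20, n_controls = 10,
                                       seed = 43), g, a)
  expect_false(identical(co1$measures$value, co3$measures$value))
})

test_that("grouping is consistent with WE_FM and both strata are populated", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  co <- simulate_cohort(cohort_config(n_patients = 60, n_controls = 15,
                                      seed = 7), g, a)
  s <- co$subjects
  pat <- s[s$is_patient, ]
  expect_identical(pat$group, ifelse(pat$wefm < 100, "PR", "CR"))
  expect_true(all(c("PR", "CR") %in% pat$group))
  expect_identical(s$group[!s$is_patient], rep("HC", 15))
  expect_true(all(is.na(s$wefm[!s$is_patient])))
  expect_identical(s$hemisphere[!s$is_patient], rep("none", 15))
  expect_true(all(s$lesion_volume[!s$is_patient] == 0))
  expect_true(all(s$lesion_volume[s$is_patient] > 0))
})

test_that("near-zero noise reproduces baseline + covariate structure exactly", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  ce <- list(age = -0.004, sexM = 0.03, scanner = c(A = 0, B = 0.04, C = -0.04))
  cc <- cohort_config(n_patients = 10, n_controls = 5,
                      effect_table = default_effect_table()[0, ],
                      slope_table = default_slope_table()[0, ],
                      covariate_effects = ce,
                      noise_sd = 1e-9, intercept_sd = 1e-12, seed = 3)
  co <- simulate_cohort(cc, g, a)
  m <- co$measures
  base <- default_roi_table()
  expected <- base$baseline[match(paste(m$roi, m$measure),
                                  paste(base$roi, base$measure))] +
    ce$age * (m$age - 55) + ce$sexM * (m$sex == "M") +
    unname(ce$scanner[m$scanner])
  expect_equal(m$value, expected, tolerance = 1e-6)
})

test_that("an injected fiber-triggered deficit is recovered as a group contrast", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  eff <- data.frame(trigger = "fiber:M1", roi = "IL precentral",
                    measure = "thickness", effect = -0.2,
                    scale_by_impairment = FALSE)
  cc <- cohort_config(n_patients = 300, n_controls = 0,
                      locus_probs = c(M1 = 0.5, S1 = 0.25, putamen = 0.25),
                      effect_table = eff,
                      slope_table = default_slope_table()[0, ],
                      covariate_effects = list(age = 0, sexM = 0,
                                               scanner = c(A = 0)),
                      noise_sd = 0.02, intercept_sd = 0.02, seed = 9)
  co <- simulate_cohort(cc, g, a)
  m <- chronic_table(co$measures)
  m <- m[m$roi == "IL precentral", ]
  hit <- m$imp_M1 > 0
  contrast <- mean(m$value[hit]) - mean(m$value[!hit])
  expect_lt(abs(contrast - (-0.2)), 0.02)  # within 10% of the truth
})

test_that("visit times are jittered, increasing, and slopes shape trajectories", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  cc <- cohort_config(n_patients = 40, n_controls = 10,
                      visit_months = c(0.25, 1, 3, 7), seed = 17)
  co <- simulate_cohort(cc, g, a)
  m <- co$measures
  expect_identical(sort(unique(m$visit)), 1:4)
  one <- m[m$subject_id == m$subject_id[1] & m$roi == m$roi[1], ]
  expect_true(all(diff(one$timepoint_months[order(one$visit)]) > 0))
  # nominal +/- 20% jitter band
  for (v in 1:4) {
    tv <- m$timepoint_months[m$visit == v] / c(0.25, 1, 3, 7)[v]
    expect_true(all(tv >= 0.8 - 1e-9 & tv <= 1.2 + 1e-9))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(fraction_left = 1.5), "fraction_left")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(visit_months = c(3, 1)), "increasing")
  expect_error(cohort_config(locus_probs = c(M1 = 0.5, S1 = 0.2,
                                             putamen = 0.2)), "sum to 1")
})

test_that("ground truth sidecar supports closed-loop checks", {
  g <- std_grid_atlas$grid; a <- std_grid_atlas$atlas
  co <- simulate_cohort(cohort_config(n_patients = 12, n_controls = 4,
                                      seed = 23), g, a)
  tr <- co$truth
  expect_named(tr$loci, c("M1", "S1", "capsule", "putamen"))
  expect_identical(unname(tr$has_putamen[co$subjects$subject_id]),
                   co$subjects$has_putamen)
  expect_identical(unname(tr$locus[co$subjects$subject_id]),
                   co$subjects$locus)
  expect_equal(unname(tr$impairments[, "M1"]), co$subjects$imp_M1)
  expect_identical(tr$effect_table, default_effect_table())
})
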