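#!/usr/bin/env Rscript

# Stage 1: generate the study cohorts on the common 32^3 (2 mm) grid.
#
# Produces a cross-sectional cohort (patients + healthy controls, one
# chronic visit, 2D measure sheets with two injected patient-vs-control
# patches) and a longitudinal cohort (four visits) whose per-group slopes
# realise the four evolution patterns. Writes subject and measure tables
# plus the lesion incidence map under results/.

suppressMessages(library(lesionmap))

seed <- 1L
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

grid <- grid_spec()
atlas <- make_fiber_atlas(grid, seed = seed + 1L)
write_fiber_atlas(atlas, file.path(out, "atlas"))

cfg <- demo_run_config(seed)
cross <- simulate_cohort(do.call(cohort_config,
                                 c(cfg$cohort, list(sheet = cfg$sheet))),
                         grid, atlas)
longit <- simulate_cohort(do.call(cohort_config, cfg$longitudinal),
                          grid, atlas)

write.table(cross$subjects, file.path(out, "subjects_cross_sectional.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(chronic_table(cross$measures),
            file.path(out, "measures_chronic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(longit$measures, file.path(out, "measures_longitudinal.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

inc <- incidence_map(cross$masks)
write_volume(inc$counts, grid, file.path(out, "lesion_incidence.nii.gz"))

saveRDS(list(cross = cross, longit = longit, grid = grid, atlas = atlas,
             cfg = cfg),
        file.path(out, "cohorts.rds"))  # scratch hand-off between stages

sj <- cross$subjects
cat(sprintf("cross-sectional: %d patients (%d PR / %d CR), %d controls\n",
            sum(sj$is_patient), sum(sj$group == "PR"),
            sum(sj$group == "CR"), sum(!sj$is_patient)))
cat(sprintf("left / right lesions: %d / %d; lesioned at putamen: %d\n",
            sum(sj$hemisphere == "left"), sum(sj$hemisphere == "right"),
            sum(sj$has_putamen)))
cat(sprintf("longitudinal: %d patients over %d visits\n",
            sum(longit$subjects$is_patient),
            max(longit$measures$visit)))
cat(sprintf("peak lesion incidence: %d of %d subjects at one voxel\n",
            max(inc$counts), inc$n_subjects))
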