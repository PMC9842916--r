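#!/usr/bin/env Rscript

# Stage 3: discovery/replication mapping of patient-vs-control differences
# on the measure sheets.
#
# The patient cohort is split into a discovery and a replication sample
# (controls are shared, as in a reuse-the-controls design). Pointwise GLMs
# (group + age + sex + scanner + global measure) are corrected by
# Monte-Carlo cluster extent (voxel p < .01, cluster p < .05, FWHM 10 mm);
# retained discovery clusters become seed masks and are confirmed on the
# replication sample (p < .05, same sign). Confirmed point sets are the
# study ROIs.

suppressMessages(library(lesionmap))
out <- "results/analysis"
co <- readRDS(file.path(out, "cohorts.rds"))
cfg <- co$cfg
th <- cfg$thresholds

subjects <- co$cross$subjects
pats <- which(subjects$is_patient)
ctrl <- which(!subjects$is_patient)
ndisc <- round(length(pats) * cfg$discovery_fraction)
disc <- c(pats[seq_len(ndisc)], ctrl)
repl <- c(pats[-seq_len(ndisc)], ctrl)

rows <- list()
for (ms in names(co$cross$sheets)) {
  sh <- co$cross$sheets[[ms]]
  design <- function(r) data.frame(
    group = factor(ifelse(subjects$is_patient[r], "patient", "HC"),
                   levels = c("HC", "patient")),
    age = subjects$age[r], sex = subjects$sex[r],
    scanner = subjects$scanner[r], global = sh$global[r])
  stat <- fit_pointwise_glm(sh$values[disc, ], sh$shape, design(disc))
  stat <- monte_carlo_cluster_correct(stat, n_sims = th$n_sims,
                                      voxel_p = th$voxel_p,
                                      cluster_alpha = th$cluster_p,
                                      fwhm_mm = th$fwhm_mm,
                                      spacing_mm = cfg$sheet$spacing_mm,
                                      seed = cfg$mc_seed)
  rois <- replicate_rois(stat, sh$values[repl, ], sh$shape, design(repl))
  cat(sprintf("%-9s: %d suprathreshold clusters, %d retained, %d confirmed\n",
              ms, nrow(stat$clusters), sum(stat$clusters$retained),
              length(rois)))
  for (r in rois)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = ms, roi = r$name, sign = r$sign, seed_size = r$seed_size,
      n_points = r$n_points,
      center_i = mean(r$indices[, 1]), center_j = mean(r$indices[, 2]))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "confirmed_rois.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("injected patch centres:\n")
print(cfg$sheet$effects[, c("measure", "ci", "cj", "amplitude")])
cat("confirmed ROI centres:\n")
print(tab[, c("measure", "center_i", "center_j", "sign")])
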