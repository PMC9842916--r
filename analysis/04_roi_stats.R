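#!/usr/bin/env Rscript

# Stage 4: ROI-level inference on the chronic measure table.
#
# (a) Three-group ANCOVA (PR / CR / HC) per ROI-measure with age, sex and
#     scanner covariates, pairwise contrasts and adjusted Cohen's d.
# (b) Partial correlations between ROI measures and WE_FM per hemisphere
#     lesion group (age/sex/scanner controlled), BY-FDR over the family.
# (c) Partial correlations between each CST subset's impairment and ROI
#     measures, controlling the other subsets, BY-FDR over ROIs x subsets.

suppressMessages(library(lesionmap))
out <- "results/analysis"
co <- readRDS(file.path(out, "cohorts.rds"))
chronic <- chronic_table(co$cross$measures)

rms <- unique(chronic[, c("roi", "measure")])
anc <- do.call(rbind, lapply(seq_len(nrow(rms)), function(i) {
  sub <- chronic[chronic$roi == rms$roi[i] & chronic$measure == rms$measure[i], ]
  cbind(roi = rms$roi[i], measure = rms$measure[i],
        ancova_three_group(sub$value, sub$group,
                           sub[, c("age", "sex", "scanner")]))
}))
write.table(anc, file.path(out, "ancova.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- anc[anc$p < 0.05, ]
cat(sprintf("ANCOVA: %d of %d pairwise contrasts at p < .05; largest |d| = %.2f (%s, %s)\n",
            nrow(sig), nrow(anc), max(abs(anc$d)),
            anc$roi[which.max(abs(anc$d))], anc$pair[which.max(abs(anc$d))]))

pat <- chronic[chronic$group != "HC", ]
for (h in c("left", "right")) {
  we <- wefm_correlations(pat[pat$hemisphere == h, ], q = 0.05)
  cst <- cst_correlations(pat[pat$hemisphere == h, ], q = 0.05)
  write.table(we, file.path(out, sprintf("wefm_correlations_%s.tsv", h)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cst, file.path(out, sprintf("cst_correlations_%s.tsv", h)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s group: %d WE_FM correlations BY-significant; CST family rejections:\n",
              h, sum(we$reject)))
  print(cst[which(cst$reject), c("roi", "measure", "subset", "pr",
                                 "corrected_p")])
}
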