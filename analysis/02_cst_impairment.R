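#!/usr/bin/env Rscript

# Stage 2: slice-wise CST impairment percentages.
#
# For every patient, the lesion is intersected with each ipsilesional CST
# fiber subset (M1/PMC/SMA/S1 origins); the impairment percentage is the
# maximum over axial slices of overlap area / tract area in that slice.

suppressMessages(library(lesionmap))
out <- "results/analysis"
co <- readRDS(file.path(out, "cohorts.rds"))

pats <- co$cross$subjects[co$cross$subjects$is_patient, ]
prof <- impairment_table(co$cross$masks[pats$subject_id], co$atlas,
                         pats$hemisphere)
write.table(prof, file.path(out, "cst_impairment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

wide <- reshape(prof[, c("subject_id", "subset", "percentage")],
                idvar = "subject_id", timevar = "subset",
                direction = "wide")
cat("patients with any impairment per subset:\n")
print(colSums(wide[, -1] > 0))
cat("mean impairment among impaired (percent):\n")
print(round(vapply(wide[, -1], function(x) mean(x[x > 0]), numeric(1)), 1))
# impairment feeds motor outcome: WE_FM should fall with M1 damage
m1 <- wide$percentage.M1[match(pats$subject_id, wide$subject_id)]
cat(sprintf("cor(WE_FM, M1 impairment) = %.2f\n", cor(pats$wefm, m1)))
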