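#!/usr/bin/env Rscript

# Runs the whole analysis in order. Equivalent one-call form:
#   lesionmap::run_pipeline(lesionmap::demo_run_config(1), "results/pipeline")

for (f in sprintf("analysis/%02d_%s.R", 1:6,
                  c("simulate", "cst_impairment", "cluster_glm",
                    "roi_stats", "vlsm", "longitudinal"))) {
  cat("\n==>", f, "\n")
  source(f, local = new.env())
}
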