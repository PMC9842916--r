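Package: lesionmap
Title: Lesion-to-Cortex Statistical Mapping for Subcortical Stroke Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating subcortical stroke lesions to cortical
    structural change. Implements slice-wise corticospinal-tract impairment
    scoring from binary lesion masks and a fiber atlas, continuous-outcome
    voxel-based lesion-symptom mapping with voxel-level false-discovery-rate
    control and cluster reporting, mass-univariate group-difference mapping
    with Monte-Carlo cluster-extent correction and discovery-replication
    region-of-interest confirmation, region-level ANCOVA and partial
    correlation with Benjamini-Yekutieli correction, and random-intercept
    linear mixed-effects comparison of longitudinal trajectories. A seeded
    synthetic-cohort generator with known injected effects makes every stage
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
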