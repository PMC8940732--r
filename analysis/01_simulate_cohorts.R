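#!/usr/bin/env Rscript

# Step 1: generate the synthetic study data.
#
# Three chronic-pain-like case-control cohorts (emulating the osteoarthritis,
# chronic low back pain and fibromyalgia samples: modest case groups, shared
# remodelling pattern) plus a comparison cohort with an unrelated effect map
# (standing in for the major-depression contrast).  All four share one
# anatomical template, so healthy-control MS topography replicates across
# datasets.  Effect maps are built anticorrelated with healthy-control
# regional MS ("hub susceptibility") with a shared cross-condition component
# plus condition noise.  Everything is written under results/cohorts/.

library(morphosim)

seed <- 20260927L
dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)

# Healthy-control baseline from a pilot draw of the shared template
pilot <- simulate_cohort(morph_sim_config(2, 40, seed = seed))
ctrl_ms <- colMeans(ms_pipeline(
  pilot$subjects[pilot$metadata$group == "control"])$regional)

set.seed(seed + 1)
shared <- as.numeric(scale(-0.7 * as.numeric(scale(ctrl_ms)) + 0.3 * rnorm(68)))

cohort_specs <- list(
  oa_like   = list(n_case = 56, n_ctrl = 20, mix = 0.8),
  clbp_like = list(n_case = 29, n_ctrl = 33, mix = 0.8),
  fm_like   = list(n_case = 20, n_ctrl = 20, mix = 0.8),
  mdd_like  = list(n_case = 19, n_ctrl = 20, mix = -0.3))  # weakly opposed

truths <- list()
for (nm in names(cohort_specs)) {
  sp <- cohort_specs[[nm]]
  set.seed(seed + match(nm, names(cohort_specs)))
  eff <- as.numeric(scale(sp$mix * shared +
                            sqrt(1 - sp$mix^2) * rnorm(68))) * 0.02
  cfg <- morph_sim_config(sp$n_case, sp$n_ctrl, effect_map = eff,
                          seed = seed + 10 + match(nm, names(cohort_specs)))
  coh <- simulate_cohort(cfg)
  write_cohort(coh$subjects, coh$metadata, file.path("results/cohorts", nm))
  truths[[nm]] <- list(effect_map = eff, deltas = coh$truth$deltas,
                       spread = coh$truth$spread)
  message(sprintf("%-10s %d cases / %d controls written (|effect| up to %.3f)",
                  nm, sp$n_case, sp$n_ctrl, max(abs(eff))))
}

saveRDS_path <- "results/cohorts/truth.json"
jsonlite::write_json(truths, saveRDS_path, auto_unbox = TRUE, digits = NA)
message("planted truth recorded in ", saveRDS_path)
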