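#!/usr/bin/env Rscript
# Stage 4 — point-wise randomization TANOVA.
#
# Paired comparison of the GFP-normalized group-mean topographies of all
# deviant faces vs all deviant butterflies (colour collapsed) at every
# timepoint, with subject-level condition swaps as the null. Reports the
# significant windows of topographic dissimilarity.

source("analysis/config.R")

sim <- analysis_sim()
conds <- analysis_conditions()
evokeds <- load_evokeds(sim$montage)
dev <- conds[conds$role != "standard", ]

pool <- function(category) {
  ids <- dev$condition_id[dev$category == category]
  lapply(evokeds, function(subj) rereference_average(grand_average(subj[ids])))
}

res <- tanova(pool("face"), pool("butterfly"),
              n_perm = 1000, seed = ANALYSIS_SEED + 1, alpha = 0.05,
              min_duration = 10)
print(res)
write_tanova(res, file.path(RESULTS_DIR, "tanova.tsv"),
             file.path(RESULTS_DIR, "tanova_windows.json"))
cat(sprintf("wrote %s/tanova.tsv and tanova_windows.json\n", RESULTS_DIR))
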