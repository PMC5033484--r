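#!/usr/bin/env Rscript
# Stage 1 — simulate the oddball study: trial sequences, behaviour, montage.
#
# Verifies the design arithmetic (standard/deviant counts per block, stimulus
# set size) and summarizes the planted behavioural effects, then writes the
# event and behaviour tables and the electrode locations under results/.

source("analysis/config.R")

design <- analysis_design()
sim <- analysis_sim()

set.seed(ANALYSIS_SEED)
subject_seeds <- sample.int(.Machine$integer.max - 1L, sim$n_subjects)

cat("— design arithmetic —\n")
full <- design_config()   # study-scale design, for the printed counts
blk <- build_block_sequence(full, 1, ANALYSIS_SEED)
cat(sprintf("study-scale block: %d standards, %d non-targets, %d targets\n",
            sum(blk$role == "standard"), sum(blk$role == "nontarget"),
            sum(blk$role == "target")))
cat(sprintf("stimulus set: %d images\n", nrow(enumerate_stimuli(full))))

cat("\n— simulated behaviour (analysis scale) —\n")
all_trials <- list(); all_beh <- list()
for (s in seq_len(sim$n_subjects)) {
  set.seed(subject_seeds[s])
  trials <- dplyr::bind_rows(lapply(seq_len(design$n_blocks), function(b) {
    tr <- build_block_sequence(design, b, subject_seeds[s] %% 1000000L + b)
    tr$subject <- s
    tr
  }))
  beh <- simulate_behavior(trials, sim$behavior, subject = s)
  all_trials[[s]] <- trials
  all_beh[[s]] <- beh
}
trials <- dplyr::bind_rows(all_trials)
beh <- dplyr::bind_rows(all_beh)

dev <- beh[beh$role != "standard", ]
agg <- dplyr::summarise(dplyr::group_by(dev, role),
                        accuracy = mean(correct),
                        rt = mean(rt_ms[correct & rt_ms >= 100]), .groups = "drop")
print(as.data.frame(agg), digits = 4)

write_events(trials, file.path(RESULTS_DIR, "events.tsv"))
write_events(beh, file.path(RESULTS_DIR, "behavior.tsv"))
write_sfp(sim$montage, file.path(RESULTS_DIR, "montage.sfp"))
cat(sprintf("\nwrote %s/{events,behavior}.tsv and montage.sfp\n", RESULTS_DIR))
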