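# Shared configuration for the numbered analysis scripts.
#
# The study is simulated at a reduced but statistically faithful scale:
# 12 subjects (19 in the emulated design), 250 Hz sampling (1 kHz), and
# blocks of 160 standards + 20 non-target + 20 target deviants (640/80/80).
# Component latencies, topographies, condition effects, blink model and
# behavioural parameters keep their study-scale defaults. Everything below
# derives deterministically from ANALYSIS_SEED.

library(erpstates)

ANALYSIS_SEED <- 20161
RESULTS_DIR <- "results"
EVOKED_DIR <- "scratch/evoked"   # regenerable intermediates (02 writes, 03-05 read)

analysis_design <- function() {
  design_config(n_standards_per_block = 160,
                n_nontarget_deviants = 20,
                n_target_deviants = 20)
}

analysis_sim <- function() {
  sim_config(n_subjects = 12, sampling_rate = 250, noise_sd = 8)
}

analysis_conditions <- function() {
  d <- analysis_design()
  rr <- d$role_rotation
  std <- unique(rr[rr$role == "standard", c("category", "colour")])
  std$role <- "standard"
  dev <- expand.grid(role = c("nontarget", "target"),
                     category = d$categories, colour = d$colours,
                     stringsAsFactors = FALSE)
  tab <- rbind(std[, c("role", "category", "colour")], dev)
  tab$condition_id <- paste(tab$role, tab$category, tab$colour, sep = "_")
  tibble::as_tibble(tab)
}

evoked_path <- function(subject, condition_id) {
  file.path(EVOKED_DIR, sprintf("s%02d_%s.tsv", subject, condition_id))
}

load_evokeds <- function(montage) {
  conds <- analysis_conditions()
  n_subj <- analysis_sim()$n_subjects
  lapply(seq_len(n_subj), function(s) {
    out <- lapply(conds$condition_id, function(id) read_evoked(evoked_path(s, id), montage))
    names(out) <- conds$condition_id
    out
  })
}

dir.create(RESULTS_DIR, showWarnings = FALSE)
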